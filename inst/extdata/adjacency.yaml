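# Anatomical adjacency of head-and-neck artery segments: which labels may
# legally join at a junction. Editable; used by connect_and_extend().
adjacency:
  - [CCA, ICA]
  - [CCA, ECA]
  - [ICA, MCA]
  - [ICA, ACA]
  - [VA, BA]
  - [BA, PCA]
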