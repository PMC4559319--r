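# Example run configuration: two-target multistable design, toy engine.
targets:
  - "((((((((....))))))))"
  - "(((((((....))))))).."
ga:
  pop_size: 50
  max_generations: 100
  seed: 7
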