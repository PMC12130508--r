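# Desk profile: the full 9-channel pipeline at laptop scale — small filter
# banks and 100 epochs. The 512-coalition grid is feasible but long (hours).
device: phone
n_subjects: 22
n_repetitions: 10
duration_steps: 200
seed: 1
target_length: 200
input_length: 100
architecture: fcn
filters: [16, 32, 16]
train:
  epochs: 100
  batch_size: 16
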