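# Reference profile: the full-scale study conditions — 427 subjects x 10
# repetitions with the 23-record missing pattern, 1000-step records, full
# filter banks and the reference hyper-parameters (learning rate 1e-5,
# 1500 epochs, per-architecture optimizers). The 512-coalition grid at this
# scale is a long-running batch job; expect days of CPU time.
device: phone
n_subjects: 427
n_repetitions: 10
duration_steps: 1000
missing: phone_pattern
seed: 1
target_length: 1000
input_length: 1000
architecture: fcn
train:
  paper_defaults: true
  batch_size: 16
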