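# Full default configuration. Scientific hyperparameters (train/hitl/loss/
# network sections) are the method's published settings; the synth and demo
# sections control the synthetic study conditions.
seed: 42
synth:
  image_size: 512
  n_lesions: [2, 5]
  lesion_radius: null        # null -> [image_size/16, image_size/6]
  dab_hue: [20, 40]
  background_hue: 220
  stain_jitter: 0.05
  roi_size: [1500, 2100]
  organs: [kidney, liver, spleen]
  per_organ: 4
weaklabel:
  hue_band: [15, 45]
  blue_band: [180, 260]
  sat_min: 0.15
  val_max: 0.98
  gaussian_sigma: 2
  min_area: 64
  open_radius: 2
  close_radius: 2
  fill_holes: true
  patch: 512
  stride: 256
  he: null
  ihc: null
  rot: 0
  dx: 0
  dy: 0
prep:
  train_fraction: 0.8
  size: 224
network:
  in_channels: 1
  stage_channels: [64, 128, 256, 512, 256, 128, 64]
  embed_dim: 32
  se_reduction: 16
  use_se: true
  use_film: true
  use_edge: true
  input_size: 224
loss:
  alpha: 0.3
  beta: 0.7
  epsilon: 1.0e-6
  w_bce: 0.3
  w_tversky: 0.7
  w_histo: 1.0
  w_edge: 0.4
train:
  lr: 5.0e-4
  batch_size: 8
  max_epochs: 50
  input_size: 224
  selection_metric: recall
  threshold: 0.5
hitl:
  ratio: 0.30
  min_per_class: 2
  lr: 2.0e-4
  weight_decay: 1.0e-2
  batch_size: 8
  epochs: 8
  ema_decay: 0.999
eval:
  threshold: 0.5
demo:
  image_size: 32
  organs: [kidney, liver, spleen]
  per_organ: 4
  stage_channels: [8, 16, 32, 64, 32, 16, 8]
  embed_dim: 8
  se_reduction: 4
  epochs: 6
  input_size: 32
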