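{
  "description": "Synthetic fixture: 3 slides x 60 cells, 2 channels, seed 424242, label_noise 0. Regenerable via fixture_small().",
  "synthetic": true,
  "n_cells": 180,
  "slide_means": {
    "vimentin": {
      "s01": 84.3166666666667,
      "s02": 118.533333333333,
      "s03": 92.7666666666667
    },
    "cd3": {
      "s01": 103.266666666667,
      "s02": 72.5,
      "s03": 186.95
    }
  },
  "md5": "2538499300bff5bea3b2ff625f761dec"
}
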