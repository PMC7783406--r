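{
  "name": "quikcap64-synthetic",
  "description": "Synthetic 64-channel cap montage: 10-10 style layout compressed above the fiducial plane and relaxed to near-uniform >24 mm spacing on a default adult head; channel sequence follows the standard vendor order",
  "ordered_labels": ["FP1", "FPZ", "FP2", "AF3", "AF4", "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8", "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8", "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8", "M1", "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8", "M2", "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8", "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8", "CB1", "O1", "OZ", "O2", "CB2"],
  "midline_labels": ["FPZ", "FZ", "FCZ", "CZ", "CPZ", "PZ", "POZ", "OZ"],
  "symmetric_pairs": [
    ["FP1", "FP2"],
    ["AF3", "AF4"],
    ["F1", "F2"],
    ["F3", "F4"],
    ["F5", "F6"],
    ["F7", "F8"],
    ["FC1", "FC2"],
    ["FC3", "FC4"],
    ["FC5", "FC6"],
    ["FT7", "FT8"],
    ["C1", "C2"],
    ["C3", "C4"],
    ["C5", "C6"],
    ["T7", "T8"],
    ["CP1", "CP2"],
    ["CP3", "CP4"],
    ["CP5", "CP6"],
    ["TP7", "TP8"],
    ["P1", "P2"],
    ["P3", "P4"],
    ["P5", "P6"],
    ["P7", "P8"],
    ["PO3", "PO4"],
    ["PO5", "PO6"],
    ["PO7", "PO8"],
    ["O1", "O2"],
    ["CB1", "CB2"],
    ["M1", "M2"]
  ],
  "anterior_midline": "FPZ",
  "posterior_midline": "OZ",
  "directions": {
    "FP1": [0.919224, 0.317066, 0.233445],
    "FPZ": [0.97237, 0, 0.233445],
    "FP2": [0.919224, -0.317066, 0.233445],
    "AF3": [0.885449, 0.138802, 0.443525],
    "AF4": [0.885449, -0.138802, 0.443525],
    "F7": [0.787353, 0.570594, 0.233445],
    "F5": [0.789264, 0.398315, 0.467341],
    "F3": [0.595357, 0.420946, 0.684365],
    "F1": [0.726083, 0.160466, 0.668622],
    "FZ": [0.550418, 0, 0.834889],
    "F2": [0.726083, -0.160466, 0.668622],
    "F4": [0.595357, -0.420946, 0.684365],
    "F6": [0.789264, -0.398315, 0.467341],
    "F8": [0.787353, -0.570594, 0.233445],
    "FT7": [0.532858, 0.813367, 0.233445],
    "FC5": [0.617567, 0.632063, 0.468089],
    "FC3": [0.342101, 0.58032, 0.73905],
    "FC1": [0.411366, 0.26676, 0.87156],
    "FCZ": [0.278846, 0, 0.960336],
    "FC2": [0.411366, -0.26676, 0.87156],
    "FC4": [0.342101, -0.58032, 0.73905],
    "FC6": [0.617567, -0.632063, 0.468089],
    "FT8": [0.532858, -0.813367, 0.233445],
    "T7": [0.355836, 0.79063, 0.498281],
    "C5": [0.032375, 0.64814, 0.760833],
    "C3": [0.126826, 0.384096, 0.914541],
    "C1": [-0.166965, 0.273349, 0.947314],
    "CZ": [-0.02613, 0, 0.999659],
    "C2": [-0.166965, -0.273349, 0.947314],
    "C4": [0.126826, -0.384096, 0.914541],
    "C6": [0.032375, -0.64814, 0.760833],
    "T8": [0.355836, -0.79063, 0.498281],
    "M1": [0.239373, 0.942446, 0.233445],
    "TP7": [-0.092186, 0.96799, 0.233445],
    "CP5": [0.040347, 0.857442, 0.512997],
    "CP3": [-0.261935, 0.535861, 0.802647],
    "CP1": [-0.459083, 0.263042, 0.848559],
    "CPZ": [-0.331662, 0, 0.943398],
    "CP2": [-0.459083, -0.263042, 0.848559],
    "CP4": [-0.261935, -0.535861, 0.802647],
    "CP6": [0.040347, -0.857442, 0.512997],
    "TP8": [-0.092186, -0.96799, 0.233445],
    "M2": [0.239373, -0.942446, 0.233445],
    "P7": [-0.406735, 0.883216, 0.233445],
    "P5": [-0.265504, 0.768571, 0.58207],
    "P3": [-0.53979, 0.501687, 0.675971],
    "P1": [-0.696501, 0.252817, 0.671543],
    "PZ": [-0.598445, 0, 0.801164],
    "P2": [-0.696501, -0.252817, 0.671543],
    "P4": [-0.53979, -0.501687, 0.675971],
    "P6": [-0.265504, -0.768571, 0.58207],
    "P8": [-0.406735, -0.883216, 0.233445],
    "PO7": [-0.545154, 0.706839, 0.450761],
    "PO5": [-0.751086, 0.461145, 0.472457],
    "PO3": [-0.891417, 0.18607, 0.413224],
    "POZ": [-0.801394, 0, 0.598137],
    "PO4": [-0.891417, -0.18607, 0.413224],
    "PO6": [-0.751086, -0.461145, 0.472457],
    "PO8": [-0.545154, -0.706839, 0.450761],
    "CB1": [-0.737217, 0.634046, 0.233445],
    "O1": [-0.888056, 0.396056, 0.233445],
    "OZ": [-0.97237, 0, 0.233445],
    "O2": [-0.888056, -0.396056, 0.233445],
    "CB2": [-0.737217, -0.634046, 0.233445]
  }
}
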