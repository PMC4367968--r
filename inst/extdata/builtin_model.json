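{
  "description": "built-in eye-surface regularity classifier (five ordered degeneration classes, class 4 = reference)",
  "version": "1.0",
  "classes": [0, 1, 2, 3],
  "reference_class": 4,
  "columns": ["independent", "distm", "distskew", "lognnvar"],
  "coefficients": [
    [84.366, -13.681, 20.391, -17.321],
    [60.004, -11.097, 15.005, -6.976],
    [29.07, -4.448, 7.663, -3.308],
    [1.299, 0.242, -17.746, -0.104]
  ]
}
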