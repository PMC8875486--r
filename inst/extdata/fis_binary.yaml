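input_sets:
  low:
    kind: trapezoidal
    breakpoints:
    - 0.0
    - 0.0
    - 0.2
    - 0.55
  high:
    kind: trapezoidal
    breakpoints:
    - 0.45
    - 0.8
    - 1.0
    - 1.0
output_sets:
  very_low:
    kind: triangular
    breakpoints:
    - 0.0
    - 0.125
    - 0.25
  low:
    kind: triangular
    breakpoints:
    - 0.25
    - 0.375
    - 0.5
  high:
    kind: triangular
    breakpoints:
    - 0.5
    - 0.625
    - 0.75
  very_high:
    kind: triangular
    breakpoints:
    - 0.75
    - 0.875
    - 1.0
rules:
- if:
  - low
  - low
  - low
  then: very_low
- if:
  - high
  - low
  - low
  then: low
- if:
  - low
  - high
  - low
  then: low
- if:
  - high
  - high
  - low
  then: high
- if:
  - low
  - low
  - high
  then: low
- if:
  - high
  - low
  - high
  then: high
- if:
  - low
  - high
  - high
  then: high
- if:
  - high
  - high
  - high
  then: very_high
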