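# Experiment definitions for the cylindrical-arena FPM simulations.
# Shapes are polygons in stimulus-angle coordinates (degrees) measured from
# the arena centre: vertices are [azimuth, elevation] pairs, elevation 0 is
# the arena floor, and the shape's left edge sits at azimuth 0. Names not
# defined here may refer to entries of shape_library().
arena:
  radius: 1.5
  feeder_distance: 0.6

shapes:
  rect_160x38:
    - [0, 0]
    - [160, 0]
    - [160, 38]
    - [0, 38]
  trapezoid_80:
    - [0, 0]
    - [80, 0]
    - [80, 57]
    - [0, 10]
  double_triangle:
    components:
      - [[0, 0], [70, 0], [35, 35]]
      - [[70, 0], [140, 0], [105, 35]]

experiments:
  rectangles:
    train: rect_160x38
    tests: [rect_160x38, rect_80x38, trapezoid_80]
    feeder_azimuth: 30
    n_train: 30
  nested_rectangles:
    train: rect_160x38
    tests: [rect_120x38, rect_80x38, rect_40x38]
    feeder_azimuth: 30
    n_train: 30
  composite_II:
    train: double_triangle
    tests: [double_triangle, rect_140x35, trapezoid_140x35]
    feeder_azimuth: 35
    n_train: 30
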