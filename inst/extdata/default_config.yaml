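# Default nocturnal-ethogram configuration.
#
# Pixel coordinates: origin top-left, y increasing downward, 1920 x 1080
# frame. Zone boxes are illustrative: real deployments calibrate them
# against a manually scored control period for each camera view.
#
# 'Standing' is the fallback assigned whenever the subject is in view but no
# zone rule matches. 'Swaying' is declared (with the 5-s minimum bout used
# in behavioral coding of stereotypies) but carries no zone rule: it is not
# separable by position and is instead detected from trunk-root displacement.
fps: 25
p_cutoff: 0.5
frame_size:
  width: 1920
  height: 1080
bodyparts: [head, trunk_root, trunk_tip, back, tail]
anchor_bodyparts: [head, trunk_root]
behaviors:
  - name: Standing
    default: true
  - name: Lying down
  - name: Foraging
  - name: Hay-net
  - name: Drinking
  - name: Swaying
    min_duration_s: 5
zone_rules:
  - behavior: Lying down            # body low in the frame, near the floor
    priority: 1
    constraints:
      - {bodypart: back, x_min: 300, x_max: 700, y_min: 800, y_max: 1000}
  - behavior: Foraging              # trunk tip in the foraging boxes, back wall
    priority: 2
    constraints:
      - {bodypart: trunk_tip, x_min: 1500, x_max: 1750, y_min: 600, y_max: 800}
  - behavior: Hay-net               # trunk tip reaching the net at the top
    priority: 3
    constraints:
      - {bodypart: trunk_tip, x_min: 800, x_max: 1100, y_min: 50, y_max: 250}
  - behavior: Drinking              # trunk tip at the water bowl
    priority: 4
    constraints:
      - {bodypart: trunk_tip, x_min: 100, x_max: 300, y_min: 500, y_max: 700}
# Simulator geometry: where each bodypart sits during a bout of the behavior
# (before measurement noise). Constrained bodyparts lie inside their zone.
geometry:
  Standing:
    head: [960, 430]
    trunk_root: [960, 520]
    trunk_tip: [960, 640]
    back: [1100, 400]
    tail: [1250, 420]
  Lying down:
    head: [430, 930]
    trunk_root: [470, 950]
    trunk_tip: [520, 980]
    back: [500, 900]
    tail: [620, 880]
  Foraging:
    head: [1500, 450]
    trunk_root: [1540, 520]
    trunk_tip: [1625, 700]
    back: [1350, 420]
    tail: [1200, 430]
  Hay-net:
    head: [930, 350]
    trunk_root: [940, 420]
    trunk_tip: [950, 150]
    back: [900, 500]
    tail: [750, 520]
  Drinking:
    head: [350, 450]
    trunk_root: [320, 520]
    trunk_tip: [200, 600]
    back: [500, 430]
    tail: [650, 430]
  Swaying:
    head: [960, 430]
    trunk_root: [960, 520]
    trunk_tip: [960, 640]
    back: [1100, 400]
    tail: [1250, 420]
# Sway kinematics for the simulator: lateral sinusoid on head and trunk root.
sway:
  amplitude_px: 40
  period_s: 4
  bodyparts: [head, trunk_root]
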