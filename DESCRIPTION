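Package: cprqa
Title: Chest-Compression Quality Assessment from 2-D Pose Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assesses the quality of cardiopulmonary-resuscitation (CPR)
    chest compressions from time-stamped 2-D pose-keypoint traces (shoulders,
    elbows, wrists in image-pixel coordinates). Implements a three-state
    wrist-trajectory machine that detects individual compressions and their
    bottom-to-bottom press time, converts wrist displacement to compression
    depth through a pixels-per-centimetre calibration, computes compression
    frequency as 60 divided by the press time, measures elbow extension by
    the law of cosines, classifies active-compression versus pause phases
    with a softmax classifier over keypoint motion features, tracks
    30-compression cycles with five-cycle session termination, and emits
    coded real-time feedback events (too shallow/deep, too slow/fast,
    abnormal posture). Includes a synthetic-session generator with known
    ground truth, agreement metrics against a reference device (mean
    absolute error, 0.5 cm tolerance accuracy, paired tests), and a
    command-line interface. The pose-estimation backend is pluggable and
    out of scope; any source of keypoint traces can feed the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
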