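# cardiomark

Marker-based cardiac kinematics from biplane videofluoroscopy.

Surgically implanted radiopaque markers, filmed at 500 Hz by two calibrated
X-ray cameras, are the only imaging technique that can follow individual
cardiac structures — tricuspid annulus segments, a single valve leaflet
edge, patches of ventricular epicardium — with millimetre accuracy through
the whole beat. `cardiomark` implements the complete computational chain
from 2D detections to quantitative geometry for a 35-marker
tricuspid/ventricular array (10 annular + 1 leaflet + 9 RV epicardial
spheres, 13 LV cylinders, 2 guide markers):

* **Calibration** — direct linear transform with Hartley normalization from
  an 18-hole planar plate (rows of 5/7/6 holes, identified automatically in
  unordered views), fundamental-matrix epipolar geometry, homogeneous DLT
  triangulation.
* **Tracking** — tracking-by-detection: cross-view detection pairs passing
  epipolar and reprojection gates become 3D hypotheses; a weighted directed
  acyclic graph over hypotheses is decomposed into tracklets by successive
  shortest paths (edge cost `α·‖Δx‖/Δt + β·(Δt−1) + γ·reprojection`, node
  reward −1); a second graph links tracklets into full tracks across
  occlusion gaps.
* **Identification** — the manual anatomical-labelling procedure,
  automated: shape tags split right from left heart, the leaflet is the
  fastest mover relative to the ring, and the two guide-marker doublets
  (beside annulus markers #7 and #3) seed a similarity registration refined
  by optimal bipartite matching, with a manual-override CSV as escape
  hatch.
* **Metrics** — per frame: tricuspid annular area (10-triangle fan about
  the annular centroid), leaflet opening angle α11 (at marker #10 between
  the chords to #5 and #11), signed annular heights about the
  least-squares annular plane, the annular coordinate frame (y through the
  LV apex, #3 in the x–y plane, z anterior), septal–lateral diameters
  (#3–#8; RV basal free wall to septum), apex–annulus distances (ten
  per-segment TAPSE curves), eight regional RV triangle areas with RV/LV
  surface totals, and MinTAA/MaxTAA beat landmarks.
* **Synthetic heart** — a first-class generator producing periodic
  beating-heart trajectories with analytic ground truth (raised-cosine
  contraction gains with per-structure phase lags, saddle flattening,
  exact configured annular-area amplitude) and a biplane corruption model
  (pixel noise, dropout, occlusion merging, false positives), so the whole
  pipeline is testable without animal data.

## Worked example

```r
library(cardiomark)

template <- build_default_template()
cfg      <- motion_config(n_frames = 1000)        # one beat @ 500 Hz
truth    <- set_marker_shapes(simulate_beat(template, cfg), template)
rig      <- default_camera_rig()

det <- project_and_corrupt(truth, rig, noise_px = 0.3, p_missing = 0.02,
                           fp_per_frame = 2, occlusion_radius_px = 2,
                           seed = 11)
params <- tracking_params(max_speed = derive_max_speed(template, cfg, rig, 0.3))
tracks <- track_markers(det, rig, params)
evaluate_tracking(tracks, truth)
#> Tracking evaluation:
#>   mean RMSE: 0.06899 mm
#>   completeness (min/mean): 0.999 / 0.9998
#>   min purity: 1
#>   id switches: 0 ; false tracks: 0

shapes <- track_shapes(tracks, det)
asg    <- assign_to_template(tracks$trajectories, template, shapes = shapes)
beat   <- analyze_beat(tracks$trajectories, asg, template = template)
beat
#> Beat analysis over frames [ 0 , 1000 ): MinTAA at 758 , MaxTAA at 998
#> TAA range: 512.47 - 688.95 mm^2
```

Reading: from 72,055 corrupted 2D detections the tracker reconstructs all
35 trajectories with perfect track purity and a mean error of 0.07 mm.
The annular area cycles between ~512 and ~689 mm² — the configured 25 %
excursion — and its minimum lands at beat phase 0.52 (frame 758 of a
500-frame cycle, i.e. 516 ms after the cycle start), lagging the
ventricular contraction peak as configured; with two identical beats in
the window, detection noise decides which period's extremum wins the
argmin. One full pipeline run
(`pipeline_run()`, or the `inst/cli/cardiomark` script's `pipeline`
subcommand) writes trajectory/detection/assignment/metrics CSVs and
camera/landmark/evaluation JSONs.

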