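# pentrack

Semi-supervised tracking of group-housed animals in low-frame-rate,
top-view grayscale video, with activity analytics for behaviour studies.

## The problem

Monitoring the activity of pigs (or other group-housed livestock) from a
single overhead camera is usually done with supervised computer vision,
which demands thousands of hand-labelled frames and degrades when lighting
or pen appearance changes. `pentrack` implements the alternative: a
semi-supervised pipeline that needs **no pre-labelled video** — only the
number of animals `K`, a bounding-box size, and the occasional human
correction when a tracker loses its target. It is aimed at animal
scientists who want per-individual trajectories, movement budgets and
space-use maps from ordinary farm recordings (typically 848 × 480 px at
6 frames per second).

## The method

**Motion detection.** For a pixel `(x, y)` and an inclusive frame window
`[t_b, t_l]`, motion is the mean absolute deviation of its intensity from
the window mean:

    m_{t_b,t_l}(x, y) = Σ_{t=t_b}^{t_l} | p(x,y,t) − p̄(x,y) | / (t_l − t_b)

A pixel an animal enters or leaves scores high; static background scores
zero. The **score map** at frame `t0` sums motion over flanking windows
`[t0−k, t0]` and `[t0, t0+k]` for `k = 1..2`.

**Pixels of interest (POI).** Scores are skewed — most pixels are
background — so the score map is binarized at its 99th quantile (strictly
greater). Small spurious responses (pen vibrations, activity outside the
pen) are removed by convolving the binary map with a normalized 5 × 5
Gaussian kernel and re-thresholding at 0.5; a 3 × 3 edge kernel then keeps
only the POI region **contours**.

**Identity proposal.** Contour pixels are grouped into `K` identities by
Ward agglomerative clustering under a symmetric nearest-neighbour
connectivity constraint; cluster centroids seed the trackers.

**Tracking.** Each animal is tracked by a lightweight bounding-box
tracker behind a pluggable contract: fixed-template normalized
cross-correlation (`template_ncc`) or sparse optical flow with
median-displacement aggregation (`sparse_flow`). A tracker whose
confidence falls below a floor freezes until a human **supervision
event** re-seeds it; the number of supervisions needed to complete a clip
is the method's labour cost.

**Evaluation and analytics.** Precision is the Euclidean distance between
predicted and true centres divided by the frame diagonal (the
*standardized error*, in `[0, 1]`); with the default calibration for the
reference camera geometry, 0.1 standardized error corresponds to
26.29 cm. From trajectories the package derives inter-animal distance
series, per-frame and accumulated movement, movement synchrony (Pearson
r), and a per-pixel intensity-variance heat map of pen hot spots.

A synthetic pen-scene generator (`pen_scene()`, `pen_preset()`) renders
textured elliptical agents over a textured background with exact ground
truth, so the entire pipeline is testable without farm footage.

## Worked example

```r
library(pentrack)

scene <- pen_preset("two_blob")        # 2 animals, 300 frames, 424 x 240, 6 fps
sim   <- render_scene(scene)           # frames + exact ground truth

# motion-based start-point proposal at frame 10
starts <- propose_start_points(sim$frames, 10, k = 2)
#>   animal     x     y
#> 1      0  121.  124.
#> 2      1  307.  112.

traj <- track_sequence(sim$frames, starts, tracker_config())
glance(traj)
#>   n_frames n_animals n_supervisions mean_confidence frac_lost
#> 1      300         2              0           0.992         0

evaluate_tracking(traj, sim$truth)
#>   animal mean_std median_std mean_px median_px mean_cm median_cm n_frames
#> 1 0       0.00848    0.00849    4.13      4.14    2.23      2.23      300
#> 2 1       0.0218     0.0218    10.6      10.6     5.73      5.72      300
#> 3 all     0.0151     0.0151     7.38      7.36    3.98      3.97      600
```

Both animals are tracked through all 300 frames with zero supervisions;
the mean standardized error of 0.015 is about 7.4 px (4 cm at the
reference geometry) and mostly reflects the few-pixel offset between the
proposed start point and the body centre. `autoplot(traj)`,
`plot_movement(traj)` and `autoplot(activity_heatmap(sim$frames))` draw
the trajectories, activity budgets and hot-spot map;
`movement_correlation(traj, 0, 1)` tests movement synchrony (the two
simulated animals walk independently, r ≈ −0.04, p = 0.45).

The same workflow runs from a config file or the bundled CLI:

```sh
Rscript inst/cli/pentrack run --config config.yaml
Rscript inst/cli/pentrack simulate --preset two_blob --out sim/
Rscript inst/cli/pentrack track --frames sim/ --k 2 --box 31 \
    --starts 121,124 307,112 --out traj.csv
```

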