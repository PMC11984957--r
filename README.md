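# beescan

Tracking and analysis of bumblebee scanning flights in pattern-discrimination
arenas.

Bumblebees trained to tell a plus from a multiplication pattern do not take
in the whole pattern at a glance. They fly up to a disc, hover 1–5 cm in
front of it at reduced speed, scan the lower half of the pattern with their
body held at roughly ±30° to the wall, and then either land on the feeder
(accept) or fly on (reject). `beescan` implements the complete measurement
chain behind that description, for anyone analysing fixed-camera video of a
single flying insect in an arena:

- **tracking** — background subtraction against a bee-free mask frame,
  size-filtered connected-component detection, second-moment ellipse fits
  for body orientation, nearest-neighbour linking with a jump gate, gap
  interpolation, moving-average smoothing, and projective (homography)
  pixel-to-metric calibration;
- **flight analysis** — per-frame kinematics; a landing-speed threshold
  found by 2-means clustering of near-feeder speeds (threshold = midpoint
  of the cluster centres); choice (landing/contact) detection; segmentation
  of inspections as maximal runs inside a ⌀12 cm × 10 cm ROI cylinder in
  front of each stimulus; classification of the scanned pattern regions
  (lower-left / lower-centre / lower-right / both-corners / top-other);
- **statistics** — Yates-corrected χ² for 2×2 first-choice tables; Wilcoxon
  signed-rank and rank-sum z tests (with exact-enumeration oracles for
  small n); a binomial GLMM (logit link, per-bee random intercept, via
  `lme4`) for learning curves over 10-choice blocks; a two-component
  Gaussian-mixture EM for body-yaw distributions;
- **summaries** — stimulus-centred occupancy heatmaps, probability
  distributions with bootstrap SEMs of the median, and region-proportion
  tables with the bee as the unit of replication;
- **synthetic data** — a regime-switching flight generator (approach /
  traverse / inspect / land) with full ground truth, a frame renderer for
  both cameras, and a logistic learning-choice simulator, so the whole
  pipeline is testable without any recordings.

## Worked example

```r
library(beescan)

arena <- arena_config()                       # 60 x 40 x 60 cm, 8 discs
sim   <- simulate_trial(flight_sim_config(), arena, seed = 1)
traj  <- sim$trajectory
kin   <- compute_kinematics(traj, 240)

near <- rep(FALSE, nrow(traj))                # speeds near any feeder
for (s in seq_len(nrow(arena$layout))) {
  d <- sqrt((traj$x_m - arena$layout$cx[s])^2 +
            (traj$y_m - arena$layout$cy[s])^2 + traj$z_m^2)
  near <- near | d < 0.02
}
thr     <- landing_speed_threshold(kin$speed_mps[near])
choices <- detect_choices(traj, kin, arena$layout, thr$threshold, 240)
events  <- segment_inspections(traj, kin, arena$layout, choices, 240)

cat(sprintf("landing threshold: %.3f m/s\n", thr$threshold))
cat(sprintf("%d inspections (%d accepts, %d rejects), %d choices\n",
            nrow(events), sum(events$decision == "accept"),
            sum(events$decision == "reject"), nrow(choices)))
cat(sprintf("median inspection speed: %.3f m/s; mean inspection time: %.2f s\n",
            median(kin$speed_mps[traj$regime == "inspect"]),
            mean(events$hover_s)))
print(fit_yaw_mixture(traj$yaw_deg[traj$regime == "inspect"], seed = 1))
chi <- chi2_2x2(matrix(c(8, 5, 5, 7), 2, byrow = TRUE))
cat(sprintf("first-choice chi-square: %.2f (df 1), p = %.2f\n",
            chi$statistic, chi$p.value))
```

which prints (numbers from this exact script):

```
landing threshold: 0.066 m/s
28 inspections (15 accepts, 13 rejects), 15 choices
median inspection speed: 0.108 m/s; mean inspection time: 1.46 s
2-component Gaussian mixture (n = 5006): mu = +26.9 / -33.4 deg,
  sd = 8.3 / 8.0, w = 0.50 / 0.50, logLik = -21099.6
first-choice chi-square: 0.35 (df 1), p = 0.55
```

The landing threshold separates hovering/landed frames (cluster near
0.01 m/s) from scanning flight (near 0.11 m/s); every ground-truth landing
falls inside an accept-labelled inspection. The mixture means near +27/−33°
say that while scanning, the bee keeps its body rotated about 30° away from
the wall normal — one eye towards the pattern — with roughly equal use of
the two sides. The χ² line is the test of first-inspected pattern by
training group for the 2×2 table `[[8, 5], [5, 7]]`.

A command-line wrapper for tracking, event analysis and trial simulation is
installed at `inst/scripts/beescan.R`.

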