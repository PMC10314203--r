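# motinv

Motion invariants of 2D images and 3D volumes from correlation functions.

Classifying signals without aligning them first — the situation of every
particle image in cryo-EM — calls for descriptors that are unchanged under
rotation and translation. `motinv` implements a ladder of such invariants:

* **Second order**: the radial power spectrum
  RPS(k) = ⟨|F(k⃗)|²⟩ over wavevector directions, and the radial
  distribution function RDF(t), the rotational average of the
  autocorrelation. They are a Hankel-type transform pair,
  RPS(k) = Ω_D ∫ t^(D−1) Ker_D(kt) RDF(t) dt with
  Ker_D(x) = Γ(D/2)(2/x)^(D/2−1) J_(D/2−1)(x) (J₀, sin x/x, 2J₁(x)/x for
  D = 2, 3, 4), and the transforms are mutually inverse.
* **Third order**: the bispectrum B(k⃗, q⃗) = F(k⃗)F(q⃗)F(−k⃗−q⃗) and its
  rotational average RABS(k, q, θ) in Fourier space; the rotationally
  averaged three-point function rabs(r, s, θ) in real space; and the Bessel
  kernel transforming one into the other. Mirroring a 2D image negates the
  angle coordinate — so third-order invariants separate mirror pairs that
  the RPS provably cannot.
* **Gaussian (Wilson) model closed forms**: for signals that are sums of
  identical Gaussian atoms, all of the above in closed form, including a
  symmetric triangle coordinate system (drop, short side, signed angle) in
  which every triangle formed by the atoms appears as one peak of the rabs
  landscape.
* **Fourth order**: a four-point helical probe for 3D volumes that
  distinguishes left- from right-handed point helices — chirality that no
  second- or third-order functional can see.

Synthetic generators (Gaussian mixtures, Bessel ring and angular-harmonic
patterns, noisy propeller volumes), MRC/CSV/JSON I/O and a small command
line (`inst/cli/motinv`) are included.

## Worked example

Five random points, their mirror image, and what each invariant sees:

```r
library(motinv)
set.seed(5)
pts <- point_pattern(matrix(runif(10, -1.5, 1.5), 5, 2), R = 0.05)
mir <- mirror_pattern(pts, axis = 2)

k <- seq(0, 4, by = 0.5)
rbind(original = rps_gaussian_mixture(pts, k)$values,
      mirrored = rps_gaussian_mixture(mir, k)$values)
#>          [,1]     [,2]     [,3]  [,4]     [,5]    [,6]     [,7]    [,8]     [,9]
#> original   25 20.33754 10.69793 3.704 2.025567 3.17689 4.619164 5.53149 5.360923
#> mirrored   25 20.33754 10.69793 3.704 2.025567 3.17689 4.619164 5.53149 5.360923
```

The spectra are identical (at k = 0 the RPS is N² = 25): second-order
invariants cannot tell a pattern from its mirror. The triangle table —
one row per unordered triple, C(5,3) = 10 rows — can:

```r
tab <- enumerate_triangles(pts)
head(cbind(tab[, c("i", "j", "k", "drop", "short", "theta")],
           theta_mirror = enumerate_triangles(mir)$theta), 4)
#>   i j k     drop     short      theta theta_mirror
#> 1 1 2 3 1.939849 1.0145132 -0.9346088    0.9346088
#> 2 1 2 4 1.726003 0.7508791  1.2925328   -1.2925328
#> 3 1 2 5 1.956558 1.4376944  1.3228194   -1.3228194
#> 4 1 3 4 2.175652 0.7508791 -1.2833303    1.2833303
```

Drop and short side (the rescaled median and shortest side of each
triangle) match exactly; the signed angle flips — mirroring is a sign
flip in these coordinates, which is also how the full RABS of an image
behaves under `mirror_map()`.

In 3D, chirality needs the fourth order. One hundred four-point helices
(radius 3, pitch 8 voxels) buried in Gaussian noise of amplitude 0.45 in
a 32³ volume:

```r
vol <- propeller_volume(n_copies = 100, box = 32, radius = 3, pitch = 8,
                        noise_sigma = 0.45, seed = 2)
snr_estimate(4 * 100, 32^3, 0.45)
#> [1] 6.028164

map <- four_point_scan(vol)
resonance_quality(map, at = c(3, 8))[c("peak", "ratio", "radius", "pitch")]
#> $peak
#> [1] 0.0001964217
#> $ratio
#> [1] 1.406706
#> $radius
#> [1] 3
#> $pitch
#> [1] 8
```

The SNR estimate (signal points / voxels / noise power) is about 6%, and
the scan's largest response sits at the true radius, pitch *and
handedness* — at this extreme noise level just above the fluctuation
floor (ratio ≈ 1.4). On a noise-free volume the same scan peaks two
orders of magnitude above the runner-up, and the mirrored
(negative-pitch) cell responds not at all; see the methods vignette
(`vignettes/motion-invariants.Rmd`) for the statistics of this detection
limit.

## Command line

```sh
inst/cli/motinv triangles --points pts.csv --out table.csv
inst/cli/motinv transform --in rdf.csv --direction rdf2rps --dim 3 --out rps.csv
inst/cli/motinv propeller-demo --seed 1 --out demo
```

Every command writes a JSON run record (resolved configuration + input
hashes) next to its outputs; stochastic commands are bit-reproducible
from their seed.

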