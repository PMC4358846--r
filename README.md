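# mfdfa2d

Multifractal texture descriptors for grayscale images by two-dimensional
multifractal detrended fluctuation analysis (2D MF-DFA), with a complete
texture-based identification pipeline: variance-ratio feature selection, a
heavy-tailed RBF support vector machine with cross-validation, pairwise
accuracy experiments, accuracy-as-distance hierarchical clustering, and
synthetic generators with analytic ground truth for validating every stage.

The package is aimed at quantitative image analysis of natural textures —
the motivating application is identifying plant species from leaf scans —
but nothing is leaf-specific: any surface whose roughness varies with scale
can be described.

## The method

An image is an $M \times N$ surface $X(i,j)$ of gray levels. For window
sizes $s \in [6, \min(M,N)/4]$ the surface is tiled from all four corners
into $s \times s$ segments; each segment is integrated into its double
cumulative sum, a least-squares plane $a i + b j + c$ is removed, and the
RMS residual $F(m,n,s)$ is collected. The order-$q$ fluctuation function
is the generalized mean

$$F_q(s) = \Big[ \tfrac{1}{n_s}\sum_{m,n} F(m,n,s)^q \Big]^{1/q},
\qquad F_0(s) = \exp\Big\{ \tfrac{1}{n_s}\sum_{m,n} \ln F(m,n,s) \Big\},$$

and $F_q(s) \propto s^{h(q)}$ defines the generalized Hurst exponent.
Derived quantities: the mass exponent $\tau(q) = q h(q) - 2$, generalized
dimensions $D_q = \tau(q)/(q-1)$ (with $D_1$ from a box-entropy
regression), and the singularity spectrum $\alpha(q) = \tau'(q)$,
$f(\alpha) = q\alpha - \tau(q)$ with width $\Delta\alpha$ and asymmetry
$\Delta f$. Twelve descriptors
$\{h(\pm1), h(\pm2), h(\pm3), \alpha_{\max}, \alpha_{\min}, \Delta\alpha,
\Delta f, D_1, D_2\}$ summarize one image.

For identification, descriptors are ranked by the separability index
$I_0 = \sigma_{bet}/\sigma_{in}$ (between-species SD of the species means
over the mean within-species SD), and the top three feed an SVM with the
heavy-tailed kernel $k(x,y) = \exp\{-\frac{1}{\sigma}\sum_d
|x_d^a - y_d^a|^b\}$ under stratified, seeded K-fold cross-validation.

## Worked example

```r
library(mfdfa2d)

# a multifractal test image: randomized cascade, power-compressed to gray
m   <- cascade_surface(c(0.4, 0.3, 0.2, 0.1), depth = 8, shuffle = TRUE, seed = 1)
img <- gray_surface(cascade_to_gray(m, seed = 1), source_id = "cascade-demo")
res <- mfdfa_spectrum(img)
res
#> <mfdfa_result> h(2) = 2.000, delta_alpha = 0.427, delta_f = -0.375, D1 = 2.134, D2 = 1.999

round(extract_features(img), 3)
#>        h_m3        h_m2        h_m1        h_p1        h_p2        h_p3
#>       2.058       2.045       2.033       2.010       2.000       1.990
#>   alpha_max   alpha_min delta_alpha     delta_f          D1          D2
#>       2.268       1.841       0.427      -0.375       2.134       1.999
```

$h(q)$ decreasing in $q$ and $\Delta\alpha = 0.43$ show the texture is
multifractal. The estimate is checkable: the gray mapping compresses the
cascade to weights $\propto p_i^{0.25}$, whose analytic mass exponents at
$q = -3, 2$ are $-8.151$ and $1.977$; the pipeline returns $-8.173$ and
$1.999$ from a single 256×256 realization.

```r
tab  <- make_species_dataset(3, 20, output = "features", seed = 5)
top3 <- select_top_features(compute_separability(tab), 3)
top3
#> [1] "h_m3"        "alpha_min"   "delta_alpha"
kfold_cv(tab, top3, K = 5, repeats = 2, seed = 9)
#> <cv_result> 5-fold x 2 runs: mean accuracy 0.7917 (fold sd 0.1375)
```

For image datasets, `extract_feature_table()` runs the full pipeline over a
list of surfaces, `pairwise_accuracy_matrix()` + `accuracy_clustering()`
build the species dendrogram, and `subsample_experiment()` /
`combination_comparison()` probe robustness to sample size and descriptor
choice. A thin command-line wrapper with `extract`, `separability`,
`classify`, `pairwise`, `cluster`, `subsample`, `compare-combos` and
`simulate` subcommands is installed at `inst/scripts/mfdfa-cli.R`.

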