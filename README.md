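# dricluster

Selecting the number of clusters with a **medoid-based deviation ratio
index (DRI)**, for categorical, numerical and mixed-type data.

Most cluster-number criteria either assume numeric data or need the full
`n x n` pairwise dissimilarity matrix.  The DRI needs only the `n x k`
matrix of distances from every object to the `k` final medoids of a
k-medoids partition.  With `SDW(k)` the summed distance of all objects to
their own cluster's medoid and `SDB(k)` the summed distances of all
objects to the `k - 1` medoids of the other clusters, the deviation ratio
is

    DR(k) = (SDW(k) / (n - k)) / (SDB(k) / (k - 1))

and the deviation ratio index compares consecutive solutions,

    DRI(k) = DR(k) / DR(k + 1).

The selected number of clusters is the **smallest `k` with
`DRI(k) < 1`** — the first size whose deviation ratio is already beaten
by its successor, so that adding another cluster stops paying.

The package provides:

* `block_kmedoids()` — a deterministic block-based k-medoids partitioner
  (initial medoids seeded from blocks of objects ordered by per-row
  standard deviation, then alternating nearest-medoid assignment and
  per-cluster medoid updates);
* `dri_curve()` / `select_k()` — the DR/DRI scan over a `k` range and the
  selection rules (`dri`, plus comparator rules `vrc`, `silhouette`,
  `msv`);
* dissimilarities for mixed data — Euclidean, Canberra, simple matching
  and a generalized Gower-type distance (`pairwise_distances()`,
  `medoid_distances()`), with min-max and ordinal-rank standardization
  (`minmax_standardize()`);
* comparator indices — distance-based variance ratio criterion (`vrc()`),
  silhouette widths, medoid shadow values, and external
  `clustering_accuracy()`;
* synthetic benchmark generators and a repeated-trial harness
  (`gen_numerical()`, `gen_categorical()`, `gen_mixed()`, `run_trials()`);
* a command-line front end (`inst/cli/dricluster.R`, subcommands
  `fit | curve | simulate | fixture`).

## Worked example

The packaged table `environment_scores()` holds 25 Asia-Pacific countries
scored on four environmental-health issues (air quality, water and
sanitation, heavy metals, waste management), min-max standardized:

```r
library(dricluster)
env <- environment_scores()
fit <- block_kmedoids(env, k = 3)
fit
#> Block-based k-medoids: k = 3 on n = 25 objects ( euclidean distance )
#> Medoids: TLS, CHN, PHL
#> SDW per assignment: 8.006 -> 7.137 -> 6.876 ->  6.71
#> Cluster sizes: 8, 5, 12
```

Seeding picks the three lowest-deviation countries (TLS, JPN, PHL) as
initial medoids; the refinement moves the second group's medoid to CHN,
and the within-group deviation falls from 8.0 to its converged 6.71.
Scanning `k`:

```r
curve <- dri_curve(env, indices = c("dri", "vrc", "silhouette", "msv"))
curve
#> Deviation ratio index curve (euclidean distance, n = 25)
#>   k   sdw    sdb      dr   vrc silhouette    msv    dri
#>   2 8.885  19.57 0.01974 26.19     0.4036 0.5375 1.5222
#>   3 6.710  47.03 0.01297 37.37     0.3328 0.4665 0.8601
#>   4 6.423  60.85 0.01508 27.62     0.2253 0.4426 0.9112
#>   ...
#> DRI rule selects k = 3
```

`DRI(2) = 1.52 >= 1` but `DRI(3) = 0.86 < 1`, so the DRI rule selects
**three clusters** (`DR(3) = 0.0130` from `SDW = 6.71`, `SDB = 47.0`);
the variance-ratio maximum agrees, while the silhouette maximum would
pick 2.  The three groups are the compact low-score cluster around TLS,
the high-score cluster around CHN and the intermediate cluster around
PHL.

The same run from the shell:

```sh
Rscript inst/cli/dricluster.R fixture --out env.csv
Rscript inst/cli/dricluster.R curve --input env.csv --schema env_schema.json \
    --standardize none --kmax 10 --out curve.tsv
```

## Synthetic recovery experiments

`run_trials()` draws repeated datasets with known `k` from three families
(two-group binary, three bivariate Gaussians at `(0,0)/(0,5)/(5,-3)`,
five-group mixed) and tallies the `k` selected by the DRI rule:

```r
run_trials("numerical", trials = 50, base_seed = 1)
#> Cluster-number recovery over repeated synthetic trials
#>      family true_k trials le_km2 km1  k kp1 ge_kp2 none
#> 1 numerical      3     50      0   1 41   4      4    0
#> Overall correct: 41 / 50 (82.0%)
```

The vignette (`vignettes/deviation-ratio-index.Rmd`) documents the index,
the algorithm, the generator designs and their limitations — in
particular why the five-group mixed family is structurally hard for any
method driven by two binary variables.

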