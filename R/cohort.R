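#' Ground-truth specification for a synthetic cohort
#'
#' Bundles the parameters of the latent connectivity model that the
#' synthetic cohort generator samples from: a Watts-Strogatz small-world
#' graph shared by the control group, a triangle-enriched perturbation of it
#' for the patient group, and the coupling strength that maps latent
#' topology onto BOLD-like correlations.
#'
#' @param n_regions number of network nodes (brain regions).
#' @param lattice_degree even number of nearest neighbours each node is
#'   wired to in the underlying ring lattice.
#' @param rewire_prob Watts-Strogatz rewiring probability in `[0, 1]`.
#' @param coupling scalar in `[0, 1/lambda_max)` scaling how strongly latent
#'   edges translate into correlation; larger values give stronger, less
#'   noisy functional connectivity.
#' @param group_effect fraction of extra triangle-closing edges planted in
#'   the patient-group graph (0 = no group difference).
#' @param seed integer master seed for the cohort.
#' @return an object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(n_regions = 116, lattice_degree = 8,
                              rewire_prob = 0.25, coupling = 0.1,
                              group_effect = 0.15, seed = 1L) {
  stopifnot(n_regions >= 4, lattice_degree %% 2 == 0,
            lattice_degree < n_regions,
            rewire_prob >= 0, rewire_prob <= 1,
            coupling >= 0, group_effect >= 0, group_effect <= 1)
  structure(list(n_regions = as.integer(n_regions),
                 lattice_degree = as.integer(lattice_degree),
                 rewire_prob = rewire_prob, coupling = coupling,
                 group_effect = group_effect, seed = as.integer(seed)),
            class = "ground_truth_spec")
}

#' Watts-Strogatz small-world graph
#'
#' Ring lattice on `n` nodes, each joined to its `k` nearest neighbours,
#' with every edge's far endpoint rewired to a uniformly chosen node with
#' probability `p` (rejecting self-loops and duplicate edges, so the edge
#' count `n*k/2` is preserved for every `p`).
#'
#' @param n number of nodes (at least 4).
#' @param k even lattice degree, `k < n`.
#' @param p rewiring probability in `[0, 1]`.
#' @param seed integer seed; same arguments always give the same graph.
#' @return binary symmetric adjacency matrix with zero diagonal.
#' @export
make_small_world_graph <- function(n, k, p, seed = NULL) {
  stopifnot(n >= 4)
  if (k %% 2 != 0) stop("lattice degree k must be even")
  if (k >= n) stop("lattice degree k must be smaller than n")
  if (p < 0 || p > 1) stop("rewiring probability must lie in [0, 1]")
  with_seed(seed, {
    adj <- matrix(0L, n, n)
    for (j in seq_len(k / 2)) {
      idx <- cbind(seq_len(n), (seq_len(n) + j - 1L) %% n + 1L)
      adj[idx] <- 1L
      adj[idx[, 2:1]] <- 1L
    }
    if (p > 0) {
      for (j in seq_len(k / 2)) {
        for (i in seq_len(n)) {
          tgt <- (i + j - 1L) %% n + 1L
          if (adj[i, tgt] == 1L && stats::runif(1) < p) {
            free <- which(adj[i, ] == 0L)
            free <- setdiff(free, i)
            if (length(free) == 0L) next
            new <- free[sample.int(length(free), 1L)]
            adj[i, tgt] <- adj[tgt, i] <- 0L
            adj[i, new] <- adj[new, i] <- 1L
          }
        }
      }
    }
    adj
  })
}

#' Plant extra clustering in a group's latent graph
#'
#' Adds triangle-closing edges (between currently unconnected pairs of
#' nodes sharing a neighbour) until `round(effect_size * m)` edges have
#' been added, where `m` is the input edge count. Each new edge closes the
#' open triad whose endpoints currently have the smallest degree sum
#' (random tie-break), which raises the mean clustering coefficient while
#' keeping the degree distribution narrow — a diffuse increase in local
#' order rather than the growth of a few dense hubs.
#'
#' @param adj binary symmetric adjacency matrix.
#' @param effect_size fraction of edges to add, in `[0, 1]`.
#' @param seed integer seed (used only for tie-breaking).
#' @return perturbed adjacency matrix.
#' @export
perturb_group_graph <- function(adj, effect_size, seed = NULL) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj),
            effect_size >= 0, effect_size <= 1)
  if (effect_size == 0) return(adj)
  m <- sum(adj) / 2
  n_add <- round(effect_size * m)
  if (n_add == 0) return(adj)
  with_seed(seed, {
    for (e in seq_len(n_add)) {
      paths2 <- adj %*% adj
      diag(paths2) <- 0
      cand <- which(paths2 > 0 & adj == 0 & upper.tri(adj), arr.ind = TRUE)
      if (nrow(cand) == 0) {
        stop("no closable triangles remain; cannot plant requested effect")
      }
      deg <- rowSums(adj)
      degsum <- deg[cand[, 1]] + deg[cand[, 2]]
      best <- which(degsum == min(degsum))
      pick <- cand[best[sample.int(length(best), 1L)], ]
      adj[pick[1], pick[2]] <- adj[pick[2], pick[1]] <- 1L
    }
    adj
  })
}

#' Covariance implied by a latent binary graph
#'
#' Maps an adjacency matrix to a positive-definite correlation-scale
#' covariance via `(I - coupling * A)^-1`, rescaled to unit diagonal.
#' Entries decay with graph distance, so directly connected regions carry
#' the strongest correlations.
#'
#' @param adj binary symmetric adjacency matrix.
#' @param coupling non-negative scalar; must satisfy
#'   `coupling * max(eigenvalue(adj)) < 1` for positive definiteness.
#' @return symmetric positive-definite matrix with unit diagonal.
#' @export
adjacency_to_covariance <- function(adj, coupling) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj), coupling >= 0)
  if (coupling == 0) return(diag(nrow(adj)))
  lam_max <- max(abs(eigen(adj, symmetric = TRUE, only.values = TRUE)$values))
  if (coupling * lam_max >= 1) {
    stop(sprintf(
      "coupling %.4f violates the spectral bound 1/lambda_max = %.4f",
      coupling, 1 / lam_max))
  }
  s <- solve(diag(nrow(adj)) - coupling * adj)
  d <- sqrt(diag(s))
  s / outer(d, d)
}

#' Simulate a BOLD-like regional time series
#'
#' Draws `n_volumes` zero-mean multivariate Gaussian samples with the given
#' covariance; optionally band-limits each column with a zero-phase
#' Butterworth filter to emulate the low-frequency content of resting-state
#' BOLD. Linear filtering applied identically to every column leaves the
#' expected zero-lag correlation structure unchanged.
#'
#' @param cov positive-definite covariance matrix.
#' @param n_volumes number of time points (at least 50).
#' @param tr repetition time in seconds.
#' @param seed integer seed.
#' @param band length-2 pass band in Hz, or `NULL` for no filtering.
#' @param subject_id identifier stored on the result.
#' @return a [subject_ts] object.
#' @export
simulate_timeseries <- function(cov, n_volumes, tr = 2, seed = NULL,
                                band = c(0.01, 0.08), subject_id = NA) {
  stopifnot(is.matrix(cov), nrow(cov) == ncol(cov), n_volumes >= 50)
  ch <- tryCatch(chol(cov),
                 error = function(e) stop("covariance is not positive definite"))
  vals <- with_seed(seed, {
    z <- matrix(rnorm(n_volumes * nrow(cov)), n_volumes, nrow(cov))
    z %*% ch
  })
  ts <- subject_ts(vals, tr = tr, subject_id = subject_id)
  if (!is.null(band)) ts <- bandpass(ts, band[1], band[2])
  ts
}

#' Generate a two-group synthetic cohort
#'
#' Builds the control-group latent graph and its triangle-enriched patient
#' perturbation from `spec`, simulates one band-limited time series per
#' subject, draws demographics resembling a matched case-control sample,
#' and links one cognitive score linearly to a nodal network metric of the
#' subject's own functional connectivity so that partial-correlation
#' recovery is testable. Writes one TSV per subject plus a `manifest.csv`.
#'
#' @param spec a [ground_truth_spec].
#' @param n_per_group subjects per group (at least 2).
#' @param n_volumes raw time points per subject (default 185; the pipeline
#'   drops the first 10 by default, retaining 175).
#' @param dir output directory (created; refuses to reuse a non-empty one
#'   unless `overwrite = TRUE`).
#' @param seed integer master seed; overrides `spec$seed` when given.
#' @param score_link list describing the planted score-metric link:
#'   `region` (node index), `sparsity` (threshold at which the nodal degree
#'   is read off), `intercept`, `beta`, `noise_sd`.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return the manifest `data.frame` (invisibly), with attribute
#'   `"ground_truth"` holding the two latent adjacency matrices.
#' @export
generate_cohort <- function(spec = ground_truth_spec(), n_per_group = 30,
                            n_volumes = 185, dir, seed = NULL,
                            score_link = list(region = 28L, sparsity = 0.1,
                                              intercept = 22, beta = 0.35,
                                              noise_sd = 1),
                            overwrite = FALSE) {
  stopifnot(inherits(spec, "ground_truth_spec"), n_per_group >= 2)
  if (score_link$region < 1 || score_link$region > spec$n_regions) {
    stop("score_link$region must index a region in 1..", spec$n_regions)
  }
  seed <- seed %||% spec$seed
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    stop("cohort directory ", dir, " exists and is not empty; ",
         "use overwrite = TRUE to replace it")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  n_sub <- 2L * n_per_group
  seeds <- derive_seeds(seed, 4L + n_sub)
  g_control <- make_small_world_graph(spec$n_regions, spec$lattice_degree,
                                      spec$rewire_prob, seed = seeds[1])
  g_patient <- perturb_group_graph(g_control, spec$group_effect,
                                   seed = seeds[2])
  cov_control <- adjacency_to_covariance(g_control, spec$coupling)
  cov_patient <- adjacency_to_covariance(g_patient, spec$coupling)

  labels <- region_labels(spec$n_regions)
  group <- rep(c("patient", "control"), each = n_per_group)
  ids <- sprintf("sub-%03d", seq_len(n_sub))

  covars <- with_seed(seeds[3], cohort_covariates(n_per_group))
  files <- character(n_sub)
  metric_link <- numeric(n_sub)
  for (i in seq_len(n_sub)) {
    cv <- if (group[i] == "patient") cov_patient else cov_control
    ts <- simulate_timeseries(cv, n_volumes, tr = 2, seed = seeds[4L + i],
                              subject_id = ids[i])
    files[i] <- file.path(dir, paste0(ids[i], "_ts.tsv"))
    write_subject_ts(ts, files[i], labels = labels)
    fc <- pearson_matrix(ts)
    g <- sparsity_binarize(fc, score_link$sparsity)
    metric_link[i] <- nodal_degree(g)[score_link$region]
  }
  score <- with_seed(seeds[4], {
    score_link$intercept + score_link$beta * metric_link +
      rnorm(n_sub, sd = score_link$noise_sd)
  })

  manifest <- data.frame(subject_id = ids, group = group,
                         sex = covars$sex, age = covars$age,
                         education = covars$education, bmi = covars$bmi,
                         moca = round(score, 2),
                         recall = round(covars$recall, 2),
                         tmt_a = round(covars$tmt_a, 2),
                         file = files, stringsAsFactors = FALSE)
  attr(manifest, "seed") <- seed
  attr(manifest, "score_link") <- score_link
  attr(manifest, "ground_truth") <- list(control = g_control,
                                         patient = g_patient)
  utils::write.csv(cbind(manifest, seed = seed),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# Demographics resembling a matched middle-aged case-control sample:
# identical sex split, overlapping age/education/BMI distributions, a
# memory-like score slightly lower and a timed-test score slightly higher
# in patients. Caller seeds the RNG.
cohort_covariates <- function(n_per_group) {
  n_m <- round(0.6 * n_per_group)
  sex1 <- sample(rep(c("M", "F"), c(n_m, n_per_group - n_m)))
  sex2 <- sample(rep(c("M", "F"), c(n_m, n_per_group - n_m)))
  list(
    sex = c(sex1, sex2),
    age = c(rnorm(n_per_group, 51.8, 7.8), rnorm(n_per_group, 48.9, 5.4)),
    education = pmax(0, c(rnorm(n_per_group, 10.7, 3.8),
                          rnorm(n_per_group, 10.2, 3.3))),
    bmi = c(rnorm(n_per_group, 24.8, 3.1), rnorm(n_per_group, 24.2, 2.8)),
    recall = c(rnorm(n_per_group, 18.0, 4.4), rnorm(n_per_group, 21.2, 5.4)),
    tmt_a = pmax(10, c(rnorm(n_per_group, 67.2, 32.5),
                       rnorm(n_per_group, 50.6, 17.5)))
  )
}

region_labels <- function(n) {
  tab <- aal116_table()
  if (n == nrow(tab)) tab$abbrev else sprintf("R%03d", seq_len(n))
}

#' Read a cohort manifest written by [generate_cohort]
#'
#' @param path path to `manifest.csv` or to the cohort directory.
#' @return manifest `data.frame`.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "file")
  miss <- setdiff(need, names(mf))
  if (length(miss) > 0) {
    stop("manifest is missing required columns: ", paste(miss, collapse = ", "))
  }
  mf
}
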