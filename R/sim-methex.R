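# Methylation/expression case-control simulator with planted anomalies.
# Loci are the subjects; the two assays observe independent sample cohorts.

#' @keywords internal
#' @noRd
draw_methylation_cohort <- function(mu, class, n_tumour, n_control) {
  nl <- length(mu)
  # control locus means shift towards 0.5; the +/- sign for mid-range loci is
  # a property of this cohort's experiment and is drawn here
  mu_c <- mu
  mu_c[mu < 0.3] <- mu[mu < 0.3] + 0.2
  mu_c[mu > 0.7] <- mu[mu > 0.7] - 0.2
  mid <- mu >= 0.3 & mu <= 0.7
  mu_c[mid] <- mu[mid] + 0.2 * sample(c(-1, 1), sum(mid), replace = TRUE)
  half_width <- function(m) ifelse(class == "hypo", m / 2, (1 - m) / 2)
  draw_block <- function(centre, n) {
    w <- half_width(centre)
    matrix(stats::runif(nl * n, centre - w, centre + w), nl, n)
  }
  m <- cbind(draw_block(mu, n_tumour), draw_block(mu_c, n_control))
  list(values = pmin(pmax(m, 0), 1), # hypo control shifts can leave [0, 1]
       mu_control = mu_c)
}

#' Simulate locus methylation for a case-control cohort
#'
#' Each locus is hypo- or hyper-methylated with locus mean
#' `mu_i ~ U(0.1, 0.4)` (hypo) or `U(0.55, 0.85)` (hyper). Tumour samples
#' draw `m_ij ~ U(mu_i - mu_i/2, mu_i + mu_i/2)` for hypo loci and
#' `U(mu_i - (1 - mu_i)/2, mu_i + (1 - mu_i)/2)` for hyper loci. Control
#' samples follow the same class-specific width rule around a mean shifted
#' towards 0.5: `mu_i + 0.2` if `mu_i < 0.3`, `mu_i - 0.2` if `mu_i > 0.7`,
#' otherwise `+/- 0.2` with equal probability. Draws are clamped to
#' `[0, 1]`.
#'
#' Samples are laid out tumour-first then control in both assays.
#'
#' @param n_hypo,n_hyper Locus counts per class (defaults 300 / 700; hypo
#'   loci come first).
#' @param n_tumour,n_control Cohort sizes (defaults 50 / 50).
#' @param seed Optional integer seed.
#'
#' @return A list of class `"methex_sim"` with `methylation`
#'   (loci x samples), `locus_class`, `mu`, `sample_status_meth` and the
#'   cohort sizes; expression fields are filled in by
#'   [simulate_expression()].
#' @export
simulate_methylation <- function(n_hypo = 300, n_hyper = 700,
                                 n_tumour = 50, n_control = 50, seed = NULL) {
  for (nm in c("n_hypo", "n_hyper", "n_tumour", "n_control")) {
    check_scalar_number(get(nm), nm, 1)
  }
  with_seed(seed, {
    nl <- n_hypo + n_hyper
    class <- c(rep("hypo", n_hypo), rep("hyper", n_hyper))
    mu <- c(stats::runif(n_hypo, 0.1, 0.4), stats::runif(n_hyper, 0.55, 0.85))
    cohort <- draw_methylation_cohort(mu, class, n_tumour, n_control)
    m <- cohort$values
    dimnames(m) <- list(sprintf("locus%04d", seq_len(nl)),
                        sprintf("m%03d", seq_len(n_tumour + n_control)))
    structure(list(
      methylation = m,
      expression = NULL,
      locus_class = stats::setNames(class, rownames(m)),
      mu = stats::setNames(mu, rownames(m)),
      mu_control_meth = stats::setNames(cohort$mu_control, rownames(m)),
      sigma = NULL,
      sample_status_meth = rep(c("tumour", "control"), c(n_tumour, n_control)),
      sample_status_expr = NULL,
      n_tumour = n_tumour, n_control = n_control,
      anomaly = NULL
    ), class = "methex_sim")
  })
}

#' Simulate locus expression for an independent cohort
#'
#' The expression assay observes its own, independent case-control cohort
#' (same design: tumour-first layout, same cohort sizes). A fresh methylation
#' realization `m'` is drawn for this cohort under the same locus parameters,
#' a per-locus noise scale `sigma_i ~ U(0.5, 0.9)` is generated, and raw
#' expression is `e'_ij ~ Normal(-m'_ij, sigma_i^2)`: expression decreases
#' with methylation, reflecting the repressive action of methylation on
#' transcription. Reported expression is centred and scaled per locus.
#'
#' @param sim A `"methex_sim"` from [simulate_methylation()].
#' @param seed Optional integer seed.
#'
#' @return The `"methex_sim"` with `expression` (loci x samples, per-locus
#'   mean 0 and sd 1), `expression_raw` (pre-scaling), the cohort's
#'   conditioning methylation (`methylation_expr_cohort`), `sigma` and
#'   `sample_status_expr` populated.
#' @export
simulate_expression <- function(sim, seed = NULL) {
  stopifnot(inherits(sim, "methex_sim"))
  if (is.null(sim$methylation)) stop("methylation not simulated", call. = FALSE)
  with_seed(seed, {
    nl <- nrow(sim$methylation)
    n <- sim$n_tumour + sim$n_control
    cohort <- draw_methylation_cohort(sim$mu, sim$locus_class,
                                      sim$n_tumour, sim$n_control)
    m2 <- cohort$values
    sigma <- stats::runif(nl, 0.5, 0.9)
    e_raw <- -m2 + matrix(stats::rnorm(nl * n, 0, sigma), nl, n)
    e <- t(scale(t(e_raw)))
    dimnames(e) <- dimnames(e_raw) <- dimnames(m2) <-
      list(rownames(sim$methylation), sprintf("e%03d", seq_len(n)))
    sim$expression <- e
    sim$expression_raw <- e_raw
    sim$methylation_expr_cohort <- m2
    sim$mu_control_expr <- stats::setNames(cohort$mu_control,
                                           rownames(sim$methylation))
    sim$sigma <- stats::setNames(sigma, rownames(sim$methylation))
    sim$sample_status_expr <- rep(c("tumour", "control"),
                                  c(sim$n_tumour, sim$n_control))
    sim
  })
}

#' Plant anomalous loci into the expression data
#'
#' Chooses two disjoint contiguous segments of `segment_length` loci. In the
#' first segment the tumour-status samples' expression is replaced by
#' `-2 * e`; in the second segment the control-status samples' is. These loci
#' behave differently in expression than in methylation and are the planted
#' ground truth for anomaly detection.
#'
#' @param sim A `"methex_sim"` with expression populated.
#' @param segment_length Loci per segment (default 10).
#' @param seed Optional integer seed.
#'
#' @return The `"methex_sim"` with modified `expression`, a pristine copy in
#'   `expression_preanomaly`, and `anomaly` (list with `tumour_segment`,
#'   `control_segment` locus indices).
#' @export
insert_anomalies <- function(sim, segment_length = 10, seed = NULL) {
  stopifnot(inherits(sim, "methex_sim"))
  if (is.null(sim$expression)) stop("expression not simulated", call. = FALSE)
  check_scalar_number(segment_length, "segment_length", 1)
  nl <- nrow(sim$expression)
  if (2 * segment_length > nl) stop("segments do not fit in the locus range", call. = FALSE)
  with_seed(seed, {
    repeat {
      starts <- sample.int(nl - segment_length + 1L, 2L)
      seg1 <- seq(starts[1L], length.out = segment_length)
      seg2 <- seq(starts[2L], length.out = segment_length)
      if (length(intersect(seg1, seg2)) == 0L) break
    }
    sim$expression_preanomaly <- sim$expression
    tum <- sim$sample_status_expr == "tumour"
    sim$expression[seg1, tum] <- -2 * sim$expression[seg1, tum]
    sim$expression[seg2, !tum] <- -2 * sim$expression[seg2, !tum]
    sim$anomaly <- list(tumour_segment = seg1, control_segment = seg2)
    sim
  })
}

#' One-call methylation/expression simulation
#'
#' Chains [simulate_methylation()], [simulate_expression()] and (optionally)
#' [insert_anomalies()] with seeds derived from one master seed.
#'
#' @inheritParams simulate_methylation
#' @inheritParams insert_anomalies
#' @param anomalies Insert the two anomaly segments (default `TRUE`).
#'
#' @return A complete `"methex_sim"`.
#' @export
simulate_methex <- function(n_hypo = 300, n_hyper = 700, n_tumour = 50,
                            n_control = 50, segment_length = 10,
                            anomalies = TRUE, seed = NULL) {
  seeds <- derive_seeds(seed, 3L)
  sim <- simulate_methylation(n_hypo, n_hyper, n_tumour, n_control, seed = seeds[1L])
  sim <- simulate_expression(sim, seed = seeds[2L])
  if (anomalies) sim <- insert_anomalies(sim, segment_length, seed = seeds[3L])
  sim
}

#' Locus-by-locus dissimilarity for one assay
#'
#' Loci are the shared subjects of the two assays; each assay's samples are
#' its features. Returns the Euclidean distance between loci across the
#' chosen assay's samples.
#'
#' @param sim A `"methex_sim"`.
#' @param assay `"meth"` or `"expr"`.
#'
#' @return A `"dissimilarity"` [similarity_matrix()] over loci.
#' @export
loci_similarity <- function(sim, assay = c("meth", "expr")) {
  stopifnot(inherits(sim, "methex_sim"))
  assay <- match.arg(assay)
  m <- switch(assay, meth = sim$methylation, expr = sim$expression)
  if (is.null(m)) stop("assay '", assay, "' not simulated yet", call. = FALSE)
  euclidean_dissimilarity(m)
}

#' Average per-locus methylation-expression correlation
#'
#' For each locus, the Pearson correlation between the methylation values and
#' the expression values across matched within-cohort sample indices (tumour
#' samples occupy the same positions in both cohorts); the average over loci
#' is returned. Computed on the pre-anomaly expression when anomalies have
#' been inserted.
#'
#' @param sim A `"methex_sim"` with expression populated.
#'
#' @return A single number (the induced association is weakly negative under
#'   the default parameters).
#' @export
methex_correlation <- function(sim) {
  stopifnot(inherits(sim, "methex_sim"))
  e <- if (!is.null(sim$expression_preanomaly)) sim$expression_preanomaly else sim$expression
  if (is.null(e)) stop("expression not simulated", call. = FALSE)
  m <- sim$methylation
  n <- min(ncol(m), ncol(e))
  cors <- vapply(seq_len(nrow(m)), function(i) {
    stats::cor(m[i, seq_len(n)], e[i, seq_len(n)])
  }, numeric(1))
  mean(cors, na.rm = TRUE)
}

#' @export
print.methex_sim <- function(x, ...) {
  cat(sprintf("<methex_sim: %d loci (%d hypo / %d hyper), %d + %d samples per assay>\n",
              length(x$locus_class), sum(x$locus_class == "hypo"),
              sum(x$locus_class == "hyper"), x$n_tumour, x$n_control))
  if (!is.null(x$anomaly)) {
    cat("  anomalies: tumour-altered loci ",
        paste(range(x$anomaly$tumour_segment), collapse = "-"),
        ", control-altered loci ",
        paste(range(x$anomaly$control_segment), collapse = "-"), "\n", sep = "")
  }
  invisible(x)
}
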