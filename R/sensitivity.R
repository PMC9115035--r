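# Variance-based global sensitivity analysis: Saltelli sampling over the
# model's process parameters and Sobol index estimation (first-, second- and
# total-order) with bootstrap confidence intervals.

#' Parameter space for sensitivity analysis
#'
#' Uniform bounds of approximately +/- `span` around each parameter's central
#' estimate. The default set is the thirteen kinetic/threshold process
#' parameters of the model (world-setup, simulation-control and the
#' literature-fixed motility speeds are held fixed), with centres at the
#' package defaults. Bounds of fraction- or percentage-valued parameters are
#' capped at their logical maximum (e.g. `fe2_solid_ineq` at 1).
#'
#' @param names parameter names. When `centers` is `NULL` they must be
#'   [world_config()] parameters (centres are then the package defaults);
#'   with explicit `centers` or `lower`/`upper`, arbitrary names are allowed
#'   (e.g. analytic test functions).
#' @param centers central estimates (default: package defaults).
#' @param span half-width of the relative bounds (default 0.2).
#' @param lower,upper explicit bounds overriding the `span` construction.
#' @return object of class `param_space`: list with `names`, `centers`,
#'   `lower`, `upper`.
#' @export
param_space <- function(names = NULL, centers = NULL, span = 0.2,
                        lower = NULL, upper = NULL) {
  if (is.null(names)) {
    names <- c("iron_per_cubicnm", "mineral_aggregation_probability",
               "contact_reduction_rate", "fe2_ads_tolerance",
               "np_mineral_reduction_ratio", "abiotic_oxidation_ratio",
               "np_attachment_threshold", "np_dissociation_threshold",
               "shedding_diameter", "fe2_equilibrium_rate", "e_shuttle_range",
               "fe2_solid_ineq", "contact_oxidation_rate")
  }
  if (anyDuplicated(names)) stop("parameter names must be unique")
  k <- length(names)
  if (is.null(centers) && (is.null(lower) || is.null(upper))) {
    defaults <- default_config()
    unknown <- setdiff(names, names(defaults))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    centers <- unlist(defaults[names])
  }
  if (is.null(lower) || is.null(upper)) {
    centers <- as.numeric(centers)
    if (length(centers) != k || any(centers <= 0))
      stop("centers must be positive, one per parameter")
    lower <- centers * (1 - span)
    upper <- centers * (1 + span)
    caps <- c(mineral_aggregation_probability = 100,
              np_attachment_threshold = 100, fe2_solid_ineq = 1,
              np_dissociation_threshold = 1, fe2_equilibrium_rate = 1,
              abiotic_oxidation_ratio = 1)
    capped <- intersect(names, names(caps))
    upper[match(capped, names)] <- pmin(upper[match(capped, names)],
                                        caps[capped])
  } else {
    lower <- as.numeric(lower); upper <- as.numeric(upper)
    if (length(lower) != k || length(upper) != k)
      stop("lower and upper must have one entry per parameter")
    if (is.null(centers)) centers <- (lower + upper) / 2
  }
  if (any(lower >= upper)) stop("degenerate bounds (lower >= upper)")
  structure(list(names = names, centers = as.numeric(centers),
                 lower = lower, upper = upper),
            class = "param_space")
}

#' @export
print.param_space <- function(x, ...) {
  cat("<param_space> ", length(x$names), " parameters\n", sep = "")
  print(data.frame(parameter = x$names, lower = x$lower, center = x$centers,
                   upper = x$upper), row.names = FALSE)
  invisible(x)
}

#' Saltelli sample for second-order Sobol analysis
#'
#' Generates the N(2k + 2) parameter vectors of the second-order Saltelli
#' scheme: base matrices A and B (Latin hypercube draws mapped into the
#' bounds) plus the cross matrices AB_i and BA_i in which column i is swapped.
#' Row layout: N rows of A, then k blocks of N rows AB_1..AB_k, then k blocks
#' BA_1..BA_k, then N rows of B.
#'
#' @param space a [param_space()].
#' @param N base sample size (> 0; powers of 2 recommended).
#' @param seed RNG seed for the design draw.
#' @return numeric matrix with `N * (2k + 2)` rows and named columns;
#'   attributes `N`, `k`.
#' @export
#' @examples
#' nrow(saltelli_sample(param_space(), 500))  # 14000
saltelli_sample <- function(space, N, seed = 1L) {
  stopifnot(inherits(space, "param_space"))
  if (length(N) != 1L || N <= 0 || N != floor(N)) stop("N must be a positive integer")
  N <- as.integer(N)
  k <- length(space$names)
  set.seed(as.integer(seed))
  U <- lhs::randomLHS(N, 2L * k)
  scale01 <- function(u) sweep(sweep(u, 2, space$upper - space$lower, "*"),
                               2, space$lower, "+")
  A <- scale01(U[, 1:k, drop = FALSE])
  B <- scale01(U[, k + (1:k), drop = FALSE])
  blocks <- vector("list", 2L * k + 2L)
  blocks[[1]] <- A
  for (i in seq_len(k)) {
    AB <- A; AB[, i] <- B[, i]
    blocks[[1L + i]] <- AB
  }
  for (i in seq_len(k)) {
    BA <- B; BA[, i] <- A[, i]
    blocks[[1L + k + i]] <- BA
  }
  blocks[[2L * k + 2L]] <- B
  m <- do.call(rbind, blocks)
  colnames(m) <- space$names
  attr(m, "N") <- N
  attr(m, "k") <- k
  m
}

#' Evaluate the simulator over a design matrix
#'
#' Runs `extractor` once per design row with the row's parameter overrides
#' applied to `config`; seeds are derived deterministically from the row
#' index so identical rows under the same base seed give identical outputs.
#' Failed evaluations are recorded as NA with a warning.
#'
#' @param design matrix from [saltelli_sample()] (named columns).
#' @param extractor function `(config, schedule, seed) -> scalar`; see
#'   [extractor_last_anoxic_rate()] and [extractor_final_np_count()].
#' @param config base [world_config()] the rows override.
#' @param schedule an [oxic_schedule()].
#' @param base_seed integer; row i runs with seed `base_seed + i`.
#' @param progress print a dot every 100 rows.
#' @return numeric vector, one output per design row.
#' @export
evaluate_batch <- function(design, extractor, config = world_config(),
                           schedule = cycling_schedule(), base_seed = 1L,
                           progress = FALSE) {
  stopifnot(is.matrix(design), !is.null(colnames(design)))
  out <- numeric(nrow(design))
  for (i in seq_len(nrow(design))) {
    cfg_i <- tryCatch(modify_config(config, as.list(design[i, ])),
                      error = function(e) e)
    val <- if (inherits(cfg_i, "error")) cfg_i else
      tryCatch(extractor(cfg_i, schedule, base_seed + i),
               error = function(e) e)
    if (inherits(val, "error")) {
      warning("design row ", i, " failed: ", conditionMessage(val))
      out[i] <- NA_real_
    } else {
      out[i] <- as.numeric(val)
    }
    if (progress && i %% 100L == 0L) cat(".")
  }
  if (progress) cat("\n")
  out
}

#' Output extractor: reduction rate of the last anoxic phase
#'
#' @param config,schedule,seed passed to [run_simulation()].
#' @return mean Fe3+ reduction rate (units/tick) over the last anoxic phase.
#' @export
extractor_last_anoxic_rate <- function(config, schedule, seed) {
  res <- run_simulation(config, schedule, seed = seed)
  ph <- summarize_phases(res, schedule)
  an <- ph[ph$state == "anoxic", ]
  if (!nrow(an)) return(NA_real_)
  an$reduction_rate[nrow(an)]
}

#' Output extractor: nanoparticle count at the end of the run
#'
#' @param config,schedule,seed passed to [run_simulation()].
#' @return final number of live nanoparticles.
#' @export
extractor_final_np_count <- function(config, schedule, seed) {
  res <- run_simulation(config, schedule, seed = seed)
  res$np_count[nrow(res)]
}

#' Sobol sensitivity indices from a Saltelli evaluation
#'
#' Estimates first-order (S1, Saltelli estimator), total-order (ST, Jansen
#' estimator) and second-order (S2, closed Saltelli estimator) Sobol indices
#' from outputs ordered as produced by [saltelli_sample()] +
#' [evaluate_batch()]. Outputs are centred before estimation, making the
#' indices exactly invariant under affine rescaling. Confidence half-widths
#' come from bootstrap resampling of the base sample.
#'
#' @param y numeric vector of length `N * (2k + 2)`, no NAs.
#' @param space the [param_space()] used for the design.
#' @param N base sample size of the design.
#' @param n_boot bootstrap resamples (default 100).
#' @param conf confidence level (default 0.95).
#' @return object of class `sobol_result`: list with `names`, `S1`, `ST`
#'   (estimates), `S1_conf`, `ST_conf` (confidence half-widths), `S2`
#'   (k x k upper-triangular matrix), `S2_conf`, `variance`, `N`.
#' @export
sobol_indices <- function(y, space, N, n_boot = 100L, conf = 0.95) {
  stopifnot(inherits(space, "param_space"))
  k <- length(space$names)
  if (length(y) != N * (2L * k + 2L))
    stop("output length ", length(y), " does not match N*(2k+2) = ",
         N * (2L * k + 2L))
  if (anyNA(y)) stop("outputs contain NA; drop or re-run failed rows first")

  block <- function(j) y[(j - 1L) * N + seq_len(N)]  # j in 1..(2k+2)
  fA <- block(1L)
  fAB <- vapply(seq_len(k), function(i) block(1L + i), numeric(N))
  fBA <- vapply(seq_len(k), function(i) block(1L + k + i), numeric(N))
  fB <- block(2L * k + 2L)

  estimate <- function(idx) {
    a <- fA[idx]; b <- fB[idx]
    ab <- fAB[idx, , drop = FALSE]; ba <- fBA[idx, , drop = FALSE]
    mu <- mean(c(a, b))
    a <- a - mu; b <- b - mu; ab <- ab - mu; ba <- ba - mu
    V <- stats::var(c(a, b))
    if (!is.finite(V) || V <= .Machine$double.eps) {
      return(list(S1 = numeric(k), ST = numeric(k),
                  S2 = matrix(0, k, k), V = 0))
    }
    # averaging the A/B-symmetric estimators (both cross matrices exist in
    # the second-order scheme) roughly halves the estimator variance
    S1 <- (colMeans(b * (ab - a)) + colMeans(a * (ba - b))) / (2 * V)
    ST <- (colMeans((a - ab)^2) + colMeans((b - ba)^2)) / (4 * V)
    S2 <- matrix(NA_real_, k, k)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        Vij <- mean(ba[, i] * ab[, j] - a * b) / V
        S2[i, j] <- Vij - S1[i] - S1[j]
      }
    }
    list(S1 = S1, ST = ST, S2 = S2, V = V)
  }

  est <- estimate(seq_len(N))
  z <- stats::qnorm(0.5 + conf / 2)
  S1b <- matrix(NA_real_, n_boot, k)
  STb <- matrix(NA_real_, n_boot, k)
  if (n_boot > 0L) {
    for (r in seq_len(n_boot)) {
      idx <- sample.int(N, N, replace = TRUE)
      e <- estimate(idx)
      S1b[r, ] <- e$S1
      STb[r, ] <- e$ST
    }
  }
  conf_hw <- function(m) if (n_boot > 0L) z * apply(m, 2, stats::sd)
    else rep(NA_real_, k)

  structure(list(
    names = space$names,
    S1 = stats::setNames(est$S1, space$names),
    ST = stats::setNames(est$ST, space$names),
    S1_conf = stats::setNames(conf_hw(S1b), space$names),
    ST_conf = stats::setNames(conf_hw(STb), space$names),
    S2 = structure(est$S2, dimnames = list(space$names, space$names)),
    variance = est$V, N = N, n_boot = n_boot, conf = conf
  ), class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, ...) {
  cat("<sobol_result> N = ", x$N, ", output variance = ",
      format(x$variance, digits = 4), "\n", sep = "")
  print(data.frame(parameter = x$names,
                   S1 = round(x$S1, 4), S1_conf = round(x$S1_conf, 4),
                   ST = round(x$ST, 4), ST_conf = round(x$ST_conf, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Second-order interaction network
#'
#' Edge list of parameter pairs whose second-order Sobol index reaches
#' `threshold`, with node annotations S1, ST and the direct-effect ratio
#' S1/ST (clamped to \[0,1\]; the share of a parameter's total influence
#' that is interaction-free).
#'
#' @param result a [sobol_indices()] result.
#' @param threshold minimum S2 for an edge (default 0.01).
#' @return list with data.frames `nodes` (`parameter`, `S1`, `ST`, `ratio`)
#'   and `edges` (`source`, `target`, `weight`).
#' @export
interaction_network <- function(result, threshold = 0.01) {
  stopifnot(inherits(result, "sobol_result"))
  k <- length(result$names)
  ratio <- ifelse(result$ST > 0, pmin(1, pmax(0, result$S1 / result$ST)), 0)
  nodes <- data.frame(parameter = result$names,
                      S1 = as.numeric(result$S1), ST = as.numeric(result$ST),
                      ratio = as.numeric(ratio))
  src <- character(0); tgt <- character(0); wgt <- numeric(0)
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        s2 <- result$S2[i, j]
        if (is.finite(s2) && s2 >= threshold) {
          src <- c(src, result$names[i])
          tgt <- c(tgt, result$names[j])
          wgt <- c(wgt, s2)
        }
      }
    }
  }
  list(nodes = nodes,
       edges = data.frame(source = src, target = tgt, weight = wgt))
}

#' Write a Sobol result as JSON
#'
#' @param result a [sobol_indices()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sobol_json <- function(result, path) {
  stopifnot(inherits(result, "sobol_result"))
  x <- list(names = result$names,
            S1 = unname(result$S1), S1_conf = unname(result$S1_conf),
            ST = unname(result$ST), ST_conf = unname(result$ST_conf),
            S2 = result$S2, N = result$N, variance = result$variance)
  jsonlite::write_json(x, path, digits = NA, na = "null", auto_unbox = TRUE)
  invisible(path)
}
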