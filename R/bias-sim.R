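#' Configuration for detection-bias resampling simulations
#'
#' @param method `"site_resample"` (per-site read resampling at observed
#'   depth) or `"fraction_resample"` (pooled reads downsampled to a fraction).
#' @param c_min_grid Coverage cutoffs for the site-resampling method.
#' @param l_min_grid Editing-level cutoffs.
#' @param fraction_grid Read fractions `f` for the pooled method.
#' @param n_replicates Resampling replicates per grid point.
#' @param seed Integer seed; fixed seed + config give identical tables.
#' @return List of class `bias_sim_config`.
#' @export
bias_sim_config <- function(method = c("site_resample", "fraction_resample"),
                            c_min_grid = 5:20,
                            l_min_grid = c(0.01, 0.02, 0.05),
                            fraction_grid = seq(0.05, 1, by = 0.025),
                            n_replicates = 1000, seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(c_min_grid) > 0, length(l_min_grid) > 0,
            all(fraction_grid > 0), all(fraction_grid <= 1))
  structure(list(method = method, c_min_grid = c_min_grid,
                 l_min_grid = l_min_grid, fraction_grid = fraction_grid,
                 n_replicates = n_replicates, seed = seed),
            class = "bias_sim_config")
}

# N/S ratio of a logical N-indicator vector; +Inf when no S survives.
ns_ratio <- function(is_n) {
  s <- sum(!is_n)
  if (s == 0) Inf else sum(is_n) / s
}

# One grid point of site resampling: replicate x site binomial redraws.
resample_grid_point <- function(C, L, is_n, l_min, n_rep) {
  p <- L / C
  n_sites <- length(C)
  ratios <- vapply(seq_len(n_rep), function(r) {
    Ls <- stats::rbinom(n_sites, C, p)
    keep <- Ls / C >= l_min
    if (!any(keep)) return(NA_real_)
    ns_ratio(is_n[keep])
  }, numeric(1))
  ratios[!is.na(ratios)]
}

#' Read-resampling simulation of N/S detection bias at observed depths
#'
#' For each combination of coverage cutoff `C_min` and level cutoff `l_min`,
#' restricts to sites with observed `C >= C_min` and `l >= l_min` and, per
#' replicate, redraws each site's edited count as
#' `Binomial(C_j, L_j/C_j)` — exactly equivalent to resampling the site's
#' `C_j` reads with replacement — keeping sites whose simulated level clears
#' `l_min`. Because lowly edited (disproportionately S) sites fall below the
#' cutoff more often than they rise above it, shallow data inflate the
#' simulated N/S; the tables quantify that inflation.
#'
#' @param sites Data frame with per-site `coverage`, `edited_count` and
#'   `category` (`"N"`/`"S"`; other rows ignored). Use per-library rows or
#'   pooled per-site totals as desired.
#' @param config A [bias_sim_config()].
#' @return Long data frame: `c_min`, `l_min`, `n_sites`, `observed`,
#'   `q025`, `median`, `q975`, `relative_difference`
#'   (median simulated / observed - 1). Replicates with no surviving S site
#'   count as `+Inf` and are retained in the quantiles.
#' @export
simulate_site_resampling <- function(sites, config = bias_sim_config()) {
  sites <- sites[sites$category %in% c("N", "S") & sites$coverage > 0, , drop = FALSE]
  set.seed(config$seed)
  grid <- expand.grid(c_min = config$c_min_grid, l_min = config$l_min_grid)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    cmin <- grid$c_min[k]; lmin <- grid$l_min[k]
    sub <- sites[sites$coverage >= cmin &
                   sites$edited_count / sites$coverage >= lmin, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    obs <- ns_ratio(sub$category == "N")
    ratios <- resample_grid_point(sub$coverage, sub$edited_count,
                                  sub$category == "N", lmin,
                                  config$n_replicates)
    q <- quantile_inf(ratios, c(0.025, 0.5, 0.975))
    data.frame(c_min = cmin, l_min = lmin, n_sites = nrow(sub), observed = obs,
               q025 = q[1], median = q[2], q975 = q[3],
               relative_difference = q[2] / obs - 1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fractional-depth resampling of pooled reads
#'
#' Pools sites across libraries (per-site totals `C`, `L`), downsamples each
#' site to `round(f * C)` reads (round-half-even, so results are
#' bit-reproducible) and redraws edited counts binomially; survivors have
#' simulated level at least `l_min`. Sites downsampled to zero reads
#' contribute nothing that replicate.
#'
#' @param sites Data frame with pooled `coverage`, `edited_count`,
#'   `category`.
#' @param config A [bias_sim_config()] (uses `fraction_grid`, `l_min_grid`).
#' @return Long data frame: `f`, `l_min`, `n_sites`, `observed`, `q025`,
#'   `median`, `q975`, `relative_difference`.
#' @export
simulate_fraction_resampling <- function(sites, config = bias_sim_config(method = "fraction_resample")) {
  sites <- sites[sites$category %in% c("N", "S") & sites$coverage > 0, , drop = FALSE]
  set.seed(config$seed)
  grid <- expand.grid(f = config$fraction_grid, l_min = config$l_min_grid)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    f <- grid$f[k]; lmin <- grid$l_min[k]
    sub <- sites[sites$edited_count / sites$coverage >= lmin, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    obs <- ns_ratio(sub$category == "N")
    depth <- round(f * sub$coverage)
    usable <- depth > 0
    p <- sub$edited_count / sub$coverage
    is_n <- sub$category == "N"
    ratios <- vapply(seq_len(config$n_replicates), function(r) {
      Ls <- stats::rbinom(sum(usable), depth[usable], p[usable])
      keep <- Ls / depth[usable] >= lmin
      if (!any(keep)) return(NA_real_)
      ns_ratio(is_n[usable][keep])
    }, numeric(1))
    ratios <- ratios[!is.na(ratios)]
    q <- quantile_inf(ratios, c(0.025, 0.5, 0.975))
    data.frame(f = f, l_min = lmin, n_sites = nrow(sub), observed = obs,
               q025 = q[1], median = q[2], q975 = q[3],
               relative_difference = q[2] / obs - 1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
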