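# Sensitivity of efficiency metrics to the standard concentration:
# metric grids, rank stability and the linear-plateau demonstration.

#' Standard-concentration grid
#'
#' An ordered set of standard concentrations (molar) over which metrics are
#' tabulated. Default 0.001, 0.01, 0.1, 1, 10 M.
#'
#' @param values numeric vector of concentrations in molar, strictly
#'   increasing and positive.
#' @return object of class \code{cstd_grid}.
#' @export
cstd_grid <- function(values = c(0.001, 0.01, 0.1, 1, 10)) {
  stopifnot(is.numeric(values), length(values) >= 1L, all(values > 0),
            !is.unsorted(values, strictly = TRUE))
  structure(list(values = values), class = "cstd_grid")
}

grid_molar <- function(grid) {
  if (inherits(grid, "cstd_grid")) grid$values else as.numeric(grid)
}

#' Tabulate eta_bind over a grid of standard concentrations
#'
#' For each compound and each C-standard on the grid, the ligand efficiency
#' \eqn{\eta_{bind}(C^\circ)}. Column-to-column the values obey the affine
#' shift law \eqn{\eta(C_2) - \eta(C_1) = \log_{10}(C_2/C_1)/N_{nH}}
#' exactly, which is why perception of relative efficiency changes with the
#' unit: the shift is larger for smaller compounds.
#'
#' @param records list of \code{compound_record}s.
#' @param grid a \code{cstd_grid} or numeric vector of molar concentrations.
#' @param ctx a \code{thermo_context} (temperature only; the grid supplies
#'   C-standard).
#' @return data.frame: one row per compound, columns id, n_nh, pkd and one
#'   \code{eta_<C>} column per grid point.
#' @export
metric_grid <- function(records, grid = cstd_grid(), ctx = thermo_context()) {
  stopifnot(is_record_list(records))
  cs <- grid_molar(grid)
  out <- data.frame(id = vapply(records, `[[`, character(1), "id"),
                    n_nh = vapply(records, `[[`, integer(1), "n_nh"),
                    pkd = vapply(records, `[[`, numeric(1), "pkd"),
                    stringsAsFactors = FALSE)
  for (cm in cs) {
    cctx <- thermo_context(ctx$temperature, cm, ctx$gas_constant)
    out[[sprintf("eta_%g", cm)]] <-
      vapply(records, function(r) eta_bind(r, cctx)$value, numeric(1))
  }
  out
}

#' Rank stability of eta_bind across standard concentrations
#'
#' Ranks compounds by eta_bind at every grid point, counts order inversions
#' between consecutive grid points, reports the Kendall tau matrix across
#' the grid, and locates the crossing C-standard for every compound pair
#' whose order flips. Because eta_bind is affine in log10(C-standard),
#' crossings are exact: the pair (i, j) crosses at
#' \eqn{\log_{10} C^* = (p_i N_j - p_j N_i)/(N_i - N_j)} (p on the 1 M
#' scale). Ties are broken by compound id and reported.
#'
#' @inheritParams metric_grid
#' @return list of class \code{rank_stability_report}: \code{rankings}
#'   (data.frame id x grid of ranks, 1 = most efficient),
#'   \code{inversions} (count between consecutive grid points),
#'   \code{kendall} (tau matrix), \code{flips} (data.frame of flipped pairs
#'   with crossing C-standard), \code{ties}.
#' @export
rank_stability <- function(records, grid = cstd_grid(),
                           ctx = thermo_context()) {
  stopifnot(is_record_list(records), length(records) >= 2L)
  cs <- grid_molar(grid)
  tab <- metric_grid(records, grid, ctx)
  etacols <- grep("^eta_", names(tab))
  eta <- as.matrix(tab[, etacols, drop = FALSE])
  rownames(eta) <- tab$id
  # rank 1 = most efficient; ties broken by id for a deterministic order
  n <- length(records)
  rank_col <- function(v) {
    o <- order(-v, tab$id)
    r <- integer(n); r[o] <- seq_len(n); r
  }
  ranks <- apply(eta, 2, rank_col)
  rownames(ranks) <- tab$id
  ties <- list()
  for (k in seq_along(cs)) {
    dup <- duplicated(eta[, k]) | duplicated(eta[, k], fromLast = TRUE)
    if (any(dup)) ties[[length(ties) + 1L]] <-
      data.frame(cstd_molar = cs[k], id = tab$id[dup])
  }
  inversions <- integer(max(length(cs) - 1L, 0L))
  if (length(cs) > 1L) for (k in seq_len(length(cs) - 1L)) {
    o1 <- order(ranks[, k]); o2 <- ranks[o1, k + 1L]
    inversions[k] <- sum(vapply(seq_along(o2), function(i)
      sum(o2[seq_len(i - 1L)] > o2[i]), numeric(1)))
  }
  # grids where all compounds tie at some C-standard make tau degenerate
  # for that column; cor's zero-sd warning is expected there
  kend <- suppressWarnings(stats::cor(eta, method = "kendall"))
  # pairwise flips and their crossing points
  flips <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    oi <- sign(eta[i, ] - eta[j, ])
    if (length(unique(oi[oi != 0])) > 1L) {
      ni <- tab$n_nh[i]; nj <- tab$n_nh[j]
      pi_ <- tab$pkd[i]; pj <- tab$pkd[j]
      lcross <- if (ni != nj) (pi_ * nj - pj * ni) / (ni - nj) else NA_real_
      flips[[length(flips) + 1L]] <- data.frame(
        id_a = tab$id[i], id_b = tab$id[j],
        cross_cstd_molar = 10^lcross, stringsAsFactors = FALSE)
    }
  }
  structure(list(rankings = ranks, inversions = inversions, kendall = kend,
                 flips = if (length(flips)) do.call(rbind, flips) else
                   data.frame(id_a = character(), id_b = character(),
                              cross_cstd_molar = numeric()),
                 ties = if (length(ties)) do.call(rbind, ties) else NULL,
                 cstd_molar = cs),
            class = "rank_stability_report")
}

#' @export
print.rank_stability_report <- function(x, ...) {
  cat("<rank_stability_report>\n")
  cat("  C° grid (M):", paste(x$cstd_molar, collapse = ", "), "\n")
  cat("  inversions between consecutive grid points:",
      paste(x$inversions, collapse = ", "), "\n")
  if (nrow(x$flips)) {
    cat("  pairs whose ranking flips on the grid:\n")
    print(x$flips, row.names = FALSE)
  } else cat("  no ranking flips on the grid\n")
  invisible(x)
}

#' Linear-plateau affinity response and its eta_bind transform
#'
#' Constructs a hypothetical response of affinity (pK, 1 M scale) to
#' molecular size: linear with the given slope up to a breakpoint, constant
#' beyond it. Changing the standard concentration shifts the whole affinity
#' curve by the same constant without changing its shape, whereas the
#' eta_bind transform curve(N)/N changes shape: the plateau region decays
#' as 1/N and the shift differs at every N.
#'
#' @param slope pK units per non-hydrogen atom (> 0).
#' @param breakpoint heavy-atom count at which the plateau starts.
#' @param n_range integer range of N to tabulate, e.g. 5:60.
#' @param intercept pK at N = 0; default 0.
#' @param cstd_molar standard concentrations (molar) at which to tabulate
#'   the eta transform; default c(0.01, 0.1, 1).
#' @return data.frame with columns n_nh, pk (at 1 M) and one
#'   \code{eta_<C>} column per C-standard.
#' @export
linear_plateau_response <- function(slope, breakpoint, n_range = 5:60,
                                    intercept = 0,
                                    cstd_molar = c(0.01, 0.1, 1)) {
  stopifnot(slope > 0)
  n_range <- as.integer(n_range)
  if (breakpoint < min(n_range) || breakpoint > max(n_range))
    stop("breakpoint outside n_range", call. = FALSE)
  pk <- ifelse(n_range <= breakpoint,
               intercept + slope * n_range,
               intercept + slope * breakpoint)
  out <- data.frame(n_nh = n_range, pk = pk)
  for (cm in cstd_molar)
    out[[sprintf("eta_%g", cm)]] <- (pk + log10(cm)) / n_range
  out
}
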