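# Fragment-to-lead pair analysis: unit-independent efficiency measures,
# start-finish eta_bind differences over a C-standard grid with matched-pair
# t tests, quartile reference maps, and Ro3/Ro5 property audits.

#' Create a fragment-to-lead pair
#'
#' @param fragment,lead \code{compound_record}s for the screening hit and
#'   the optimized lead.
#' @param project_id optional project label.
#' @return object of class \code{f2l_pair}. A lead that is not larger than
#'   its fragment triggers a warning (leads surveyed in the field are
#'   larger), not an error.
#' @export
f2l_pair <- function(fragment, lead, project_id = "") {
  stopifnot(inherits(fragment, "compound_record"),
            inherits(lead, "compound_record"))
  if (lead$n_nh <= fragment$n_nh)
    warning(sprintf("pair '%s': lead (N_nH = %d) is not larger than fragment (N_nH = %d)",
                    project_id, lead$n_nh, fragment$n_nh), call. = FALSE)
  structure(list(fragment = fragment, lead = lead,
                 project_id = as.character(project_id)), class = "f2l_pair")
}

is_pair_list <- function(x)
  is.list(x) && length(x) > 0 &&
  all(vapply(x, inherits, logical(1), "f2l_pair"))

#' Molecular size efficiency of a fragment-to-lead optimization
#'
#' \eqn{\Delta pK_D / \Delta N_{nH} =
#' \log_{10}(K_D[F]/K_D[L]) / (N_{nH}[L] - N_{nH}[F])}: the affinity gained
#' per heavy atom added. The K_D ratio makes the value independent of the
#' concentration unit, unlike a difference of ligand efficiencies.
#'
#' @param pair an \code{f2l_pair}.
#' @return numeric slope (log units per atom).
#' @export
pair_mse <- function(pair) {
  stopifnot(inherits(pair, "f2l_pair"))
  dn <- pair$lead$n_nh - pair$fragment$n_nh
  if (dn == 0L)
    stop(sprintf("pair '%s': equal N_nH, size efficiency undefined",
                 pair$project_id), call. = FALSE)
  (pair$lead$pkd - pair$fragment$pkd) / dn
}

#' Lipophilicity-corrected affinity gain of a fragment-to-lead pair
#'
#' \eqn{\Delta pK_D - \Delta \log P =
#' \log_{10}\!\big((K_D[F] P[F]) / (K_D[L] P[L])\big)}: affinity gained
#' beyond what increased lipophilicity alone would suggest. Zero means the
#' gain is entirely attributable to increased hydrophobic contact; large
#' positive values are desirable. Unit-independent for the same reason as
#' \code{pair_mse}.
#'
#' @param pair an \code{f2l_pair} whose records both carry logP.
#' @return numeric value (log units).
#' @export
pair_lip_eff <- function(pair) {
  stopifnot(inherits(pair, "f2l_pair"))
  if (is.na(pair$fragment$logp) || is.na(pair$lead$logp))
    stop(sprintf("pair '%s': logP missing", pair$project_id), call. = FALSE)
  (pair$lead$pkd - pair$fragment$pkd) -
    (pair$lead$logp - pair$fragment$logp)
}

#' Start-finish ligand-efficiency change over a C-standard grid, with
#' matched-pair t tests
#'
#' For each standard concentration on the grid, computes per-pair
#' \eqn{\Delta\eta_{bind} = \eta_{bind}(lead) - \eta_{bind}(fragment)}, the
#' cohort mean, standard error (sd/sqrt(n)), matched-pair t statistic
#' (mean/SE, n-1 df) and two-sided p value. The mean is affine in
#' log10(C-standard) with slope mean(1/N_nH[lead] - 1/N_nH[fragment]), so
#' whenever leads are larger than fragments the apparent efficiency change
#' declines as C-standard increases, and its sign can reverse across the
#' grid; statistical significance likewise depends on the unit choice.
#'
#' @param pairs list of \code{f2l_pair}s (at least 3).
#' @param grid a \code{cstd_grid} or numeric vector of molar concentrations.
#' @param ctx a \code{thermo_context}.
#' @return data.frame of class \code{grid_test_result}: one row per grid
#'   point with columns cstd_molar, mean_delta_eta, se_delta_eta, t, p, n;
#'   attribute \code{slope} holds mean(1/N[L] - 1/N[F]).
#' @export
grid_paired_test <- function(pairs, grid = cstd_grid(),
                             ctx = thermo_context()) {
  if (!is_pair_list(pairs) || length(pairs) < 3L)
    stop("grid_paired_test needs at least 3 fragment-to-lead pairs",
         call. = FALSE)
  cs <- grid_molar(grid)
  n <- length(pairs)
  # delta eta at 1 M plus the affine shift per pair
  d1 <- vapply(pairs, function(p)
    p$lead$pkd / p$lead$n_nh - p$fragment$pkd / p$fragment$n_nh, numeric(1))
  shift <- vapply(pairs, function(p)
    1 / p$lead$n_nh - 1 / p$fragment$n_nh, numeric(1))
  rows <- lapply(cs, function(cm) {
    d <- d1 + log10(cm) * shift
    m <- mean(d); se <- stats::sd(d) / sqrt(n)
    tstat <- m / se
    data.frame(cstd_molar = cm, mean_delta_eta = m, se_delta_eta = se,
               t = tstat, p = 2 * stats::pt(-abs(tstat), df = n - 1), n = n)
  })
  out <- do.call(rbind, rows)
  attr(out, "slope") <- mean(shift)
  class(out) <- c("grid_test_result", "data.frame")
  out
}

#' Quartile reference map of fragment-to-lead efficiency slopes
#'
#' Five-number summary (min, Q1, median, Q3, max) of
#' \eqn{\Delta pK_D/\Delta N_{nH}} across pairs, and the same for the
#' lipophilicity-corrected gain where logP is available. The slopes define
#' reference lines through the origin in (delta N_nH, delta pK_D) space
#' against which a new optimization can be placed. Quartiles use linear
#' interpolation between order statistics (quantile type 7).
#'
#' @param pairs list of \code{f2l_pair}s (at least 5 for quartiles).
#' @return list of class \code{quartile_map} with elements \code{mse} and
#'   (possibly NULL) \code{lip_eff}, each a named numeric
#'   c(min, q1, median, q3, max), plus \code{n}.
#' @export
quartile_map <- function(pairs) {
  stopifnot(is_pair_list(pairs))
  if (length(pairs) < 5L)
    stop("quartile_map needs at least 5 pairs", call. = FALSE)
  five <- function(x) {
    q <- stats::quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7,
                         names = FALSE)
    stats::setNames(q, c("min", "q1", "median", "q3", "max"))
  }
  mse <- vapply(pairs, pair_mse, numeric(1))
  lip <- tryCatch(vapply(pairs, pair_lip_eff, numeric(1)),
                  error = function(e) NULL)
  structure(list(mse = five(mse),
                 lip_eff = if (is.null(lip)) NULL else five(lip),
                 n = length(pairs), quantile_type = 7L),
            class = "quartile_map")
}

#' @export
print.quartile_map <- function(x, ...) {
  cat("<quartile_map> n =", x$n, "pairs (quantile type 7)\n")
  cat("  ΔpK_D/ΔN_nH: ")
  print(round(x$mse, 3))
  if (!is.null(x$lip_eff)) { cat("  ΔpK_D − ΔlogP: "); print(round(x$lip_eff, 3)) }
  invisible(x)
}

#' Rule-of-five / rule-of-three property audit
#'
#' Flags each compound against the Ro5 limits (MW <= 500, logP <= 5,
#' HBD <= 5, HBA <= 10) and the fragment-screening Ro3 limits (MW <= 300,
#' logP <= 3, HBD <= 3, HBA <= 3), using Lipinski hydrogen-bond
#' definitions (donors = NH + OH counts, acceptors = N + O counts) for both
#' rules. Rules whose inputs are missing are reported "not assessable"
#' rather than pass or fail.
#'
#' @param records list of \code{compound_record}s.
#' @return data.frame: id, per-rule violation counts, pass flags,
#'   comma-separated failing fields, and assessable flags; the hydrogen-bond
#'   convention is recorded in attribute \code{hb_convention}.
#' @export
rule_audit <- function(records) {
  stopifnot(is_record_list(records))
  audit_one <- function(rec, mw_max, logp_max, hbd_max, hba_max) {
    vals <- c(mw = rec$mw, logp = rec$logp, hbd = rec$hbd, hba = rec$hba)
    lims <- c(mw = mw_max, logp = logp_max, hbd = hbd_max, hba = hba_max)
    if (anyNA(vals))
      return(list(viol = NA_integer_, pass = NA, fail_on = "",
                  assessable = FALSE))
    bad <- names(vals)[vals > lims]
    list(viol = length(bad), pass = length(bad) == 0L,
         fail_on = paste(bad, collapse = ","), assessable = TRUE)
  }
  rows <- lapply(records, function(rec) {
    r5 <- audit_one(rec, 500, 5, 5, 10)
    r3 <- audit_one(rec, 300, 3, 3, 3)
    data.frame(id = rec$id,
               ro5_violations = r5$viol, ro5_pass = r5$pass,
               ro5_fail_on = r5$fail_on, ro5_assessable = r5$assessable,
               ro3_violations = r3$viol, ro3_pass = r3$pass,
               ro3_fail_on = r3$fail_on, ro3_assessable = r3$assessable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "hb_convention") <- "Lipinski (HBD = NH+OH, HBA = N+O)"
  out
}
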