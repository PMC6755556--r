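# Compound records and per-compound efficiency metrics. Affinity is stored
# internally in molar; unit handling happens at the boundary.

#' Create a compound record
#'
#' The row type of every table in the package: an identifier, the
#' non-hydrogen (heavy) atom count, an affinity given either as a
#' concentration (K_D or IC50 with a unit) or on the p-scale (pK_D or
#' pIC50, relative to 1 M unless \code{p_ref_unit} says otherwise), and
#' optional physicochemical properties. Whichever affinity form is not
#' supplied is derived from the other. IC50-derived values carry an
#' approximation flag that propagates to metric outputs.
#'
#' @param id character identifier.
#' @param n_nh positive integer non-hydrogen atom count.
#' @param affinity a \code{dim_quantity} (dimension 1), or a numeric value
#'   combined with \code{affinity_unit}.
#' @param affinity_unit unit token for a numeric \code{affinity}.
#' @param p_affinity pK_D or pIC50 value (alternative to \code{affinity}).
#' @param p_ref_unit reference unit of \code{p_affinity}; default "M"
#'   (potency divided by 1 M).
#' @param affinity_kind one of "KD", "IC50", "pKD", "pIC50".
#' @param mw molecular weight, Da (optional).
#' @param logp,hbd,hba optional logP (or ClogP), hydrogen-bond donor and
#'   acceptor counts.
#' @return an object of class \code{compound_record} with derived fields
#'   \code{kd_molar} and \code{pkd} (p-scale relative to 1 M).
#' @examples
#' compound_record("frag", n_nh = 10, affinity = 1, affinity_unit = "mM",
#'                 affinity_kind = "KD")
#' @export
compound_record <- function(id, n_nh, affinity = NULL, affinity_unit = "M",
                            p_affinity = NULL, p_ref_unit = "M",
                            affinity_kind = c("KD", "IC50", "pKD", "pIC50"),
                            mw = NA_real_, logp = NA_real_,
                            hbd = NA_integer_, hba = NA_integer_) {
  affinity_kind <- match.arg(affinity_kind)
  if (!is.numeric(n_nh) || length(n_nh) != 1L || is.na(n_nh) ||
      n_nh < 1 || n_nh != round(n_nh))
    stop("n_nh must be a positive integer", call. = FALSE)
  has_conc <- !is.null(affinity)
  has_p <- !is.null(p_affinity) && !is.na(p_affinity)
  if (has_conc == has_p && !has_conc)
    stop("supply exactly one of affinity or p_affinity", call. = FALSE)
  if (has_conc && has_p)
    stop("supply exactly one of affinity or p_affinity", call. = FALSE)
  if (has_conc) {
    if (!inherits(affinity, "dim_quantity"))
      affinity <- dim_quantity(as.numeric(affinity), 1, affinity_unit)
    if (as_molar(affinity) <= 0)
      stop("affinity concentration must be positive", call. = FALSE)
    kd_molar <- as_molar(affinity)
    pkd <- -log10(kd_molar)
  } else {
    ref <- if (is.character(p_ref_unit)) parse_conc_unit(p_ref_unit) else
      as.numeric(p_ref_unit)
    kd_molar <- ref * 10^(-p_affinity)
    pkd <- -log10(kd_molar)
  }
  structure(list(id = as.character(id), n_nh = as.integer(n_nh),
                 kd_molar = kd_molar, pkd = pkd,
                 affinity_kind = affinity_kind,
                 approx = affinity_kind %in% c("IC50", "pIC50"),
                 mw = as.numeric(mw), logp = as.numeric(logp),
                 hbd = as.integer(hbd), hba = as.integer(hba)),
            class = "compound_record")
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound_record> %s: N_nH = %d, %s = %.4g M (pK = %.3g)%s\n",
              x$id, x$n_nh, x$affinity_kind, x$kd_molar, x$pkd,
              if (x$approx) " [IC50 approximation]" else ""))
  invisible(x)
}

is_record_list <- function(x)
  is.list(x) && length(x) > 0 && all(vapply(x, inherits, logical(1),
                                            "compound_record"))

# ---- MetricValue ----------------------------------------------------------

metric_value <- function(metric, value, c_standard = NULL,
                         temperature = NULL, approx = FALSE, note = "") {
  structure(list(metric = metric, value = value, c_standard = c_standard,
                 temperature = temperature, approx = approx, note = note),
            class = "metric_value")
}

#' @export
format.metric_value <- function(x, ...) {
  digits <- if (x$metric %in% c("DG_PER_ATOM", "GE")) 1L else 2L
  ctxt <- if (is.null(x$c_standard)) "C°-independent" else
    sprintf("C° = %s", format(x$c_standard))
  sprintf("%s = %.*f (%s)%s", x$metric, digits, x$value, ctxt,
          if (x$approx) " [IC50 approximation]" else "")
}

#' @export
print.metric_value <- function(x, ...) {
  cat("<metric_value> ", format(x), "\n", sep = ""); invisible(x)
}

#' @export
as.numeric.metric_value <- function(x, ...) x$value

resolve_kd <- function(rec) {
  if (is.null(rec$kd_molar) || is.na(rec$kd_molar) || rec$kd_molar <= 0)
    stop(sprintf("record '%s' has no usable affinity", rec$id), call. = FALSE)
  rec$kd_molar
}

#' Ligand efficiency in log units (eta_bind)
#'
#' \eqn{\eta_{bind} = -\log_{10}(K_D/C^\circ)/N_{nH}}. The value depends on
#' the standard concentration: raising C-standard tenfold raises eta_bind by
#' exactly 1/N_nH, so compounds of different size shift by different
#' amounts and rankings can change with the unit choice.
#'
#' @param rec a \code{compound_record}.
#' @param ctx a \code{thermo_context}; its \code{c_standard} is used.
#' @return a \code{metric_value} recording the C-standard used.
#' @examples
#' r <- compound_record("a", 10, affinity = 1, affinity_unit = "mM")
#' eta_bind(r, thermo_context(c_standard = 1))$value   # 0.3
#' @export
eta_bind <- function(rec, ctx = thermo_context()) {
  kd <- resolve_kd(rec)
  cm <- as_molar(ctx$c_standard)
  metric_value("ETA_BIND", -log10(kd / cm) / rec$n_nh,
               c_standard = ctx$c_standard, temperature = NULL,
               approx = rec$approx)
}

#' Ligand efficiency in energy units (free energy per heavy atom)
#'
#' \eqn{\Delta g = -\Delta G^\circ / N_{nH} = RT\ln(10)\,\eta_{bind}}, in
#' kcal/mol per non-hydrogen atom. Shares the C-standard dependence of
#' eta_bind exactly.
#'
#' @inheritParams eta_bind
#' @return a \code{metric_value} (kcal/mol per atom).
#' @export
dg_per_atom <- function(rec, ctx = thermo_context()) {
  eta <- eta_bind(rec, ctx)
  metric_value("DG_PER_ATOM", eta$value * rtln10(ctx),
               c_standard = ctx$c_standard, temperature = ctx$temperature,
               approx = rec$approx)
}

#' Invert a per-atom efficiency threshold to a p-scale affinity
#'
#' Maps a free-energy-per-atom cutoff back to the pK_D it implies at a given
#' molecular size: pK = N * dg / (RT ln 10) + log10(C-standard / 1 M). Used
#' to translate minimum-efficiency guidelines into affinity requirements.
#'
#' @param dg kcal/mol per non-hydrogen atom.
#' @param n_nh heavy-atom count at which to evaluate.
#' @param ctx a \code{thermo_context}.
#' @return numeric pK_D (relative to 1 M).
#' @export
pkd_from_dg_per_atom <- function(dg, n_nh, ctx = thermo_context()) {
  eta <- dg / rtln10(ctx)
  n_nh * eta - log10(as_molar(ctx$c_standard))
}

#' Binding efficiency index
#'
#' BEI = pIC50 (or pK_D) divided by molecular weight in kDa. The implicit
#' 1 M reference of the p-scale is recorded: BEI inherits the same
#' unit-convention dependence as the other scaled metrics.
#'
#' @inheritParams eta_bind
#' @return a \code{metric_value}.
#' @export
bei <- function(rec) {
  if (is.na(rec$mw)) stop(sprintf("record '%s' has no MW", rec$id),
                          call. = FALSE)
  metric_value("BEI", rec$pkd / (rec$mw / 1000),
               c_standard = dim_quantity(1, 1, "M"), approx = rec$approx)
}

#' Ligand efficiency by atomic number
#'
#' LEAN = pIC50 / N_nH. Numerically equal to eta_bind when the p-scale
#' reference unit equals the standard concentration; the 1 M reference in
#' use is recorded.
#'
#' @inheritParams eta_bind
#' @return a \code{metric_value}.
#' @export
lean <- function(rec) {
  metric_value("LEAN", rec$pkd / rec$n_nh,
               c_standard = dim_quantity(1, 1, "M"), approx = rec$approx)
}

#' Lipophilic ligand efficiency (LLE / LipE)
#'
#' pK_D (or pIC50) minus logP: an offset, not a scaled, measure. A common
#' change of concentration unit shifts every compound's LLE by the same
#' constant, so LLE differences between compounds are unit-invariant; the
#' 1 M reference of the stored p-scale is recorded.
#'
#' @inheritParams eta_bind
#' @return a \code{metric_value} flagged C-standard-independent (for
#'   differences).
#' @export
lle <- function(rec) {
  if (is.na(rec$logp)) stop(sprintf("record '%s' has no logP", rec$id),
                            call. = FALSE)
  metric_value("LLE", rec$pkd - rec$logp, c_standard = NULL,
               approx = rec$approx,
               note = "p-scale reference 1 M; differences unit-invariant")
}

#' Fit quality: ligand efficiency relative to a size-dependent reference
#'
#' FQ = dg_per_atom / reference(N_nH), where the reference maps heavy-atom
#' count to a reference efficiency (kcal/mol per atom). As a ratio of
#' free energies it remains dependent on the standard concentration unless
#' the reference is recomputed at the same C-standard.
#'
#' @inheritParams eta_bind
#' @param le_reference function of n_nh returning a positive reference
#'   efficiency in kcal/mol per atom.
#' @return a \code{metric_value}.
#' @export
fq <- function(rec, le_reference, ctx = thermo_context()) {
  ref <- le_reference(rec$n_nh)
  if (!is.numeric(ref) || ref <= 0)
    stop("reference efficiency must be positive", call. = FALSE)
  dg <- dg_per_atom(rec, ctx)
  metric_value("FQ", dg$value / ref, c_standard = ctx$c_standard,
               temperature = ctx$temperature, approx = rec$approx,
               note = "ratio of ΔG° values: C°-dependent")
}

#' Enthalpic efficiency
#'
#' -ΔH / N_nH. Enthalpy carries no standard-concentration dependence, so
#' this is the one per-atom efficiency that is defined unambiguously.
#'
#' @param delta_h binding enthalpy, kcal/mol.
#' @param n_nh positive integer heavy-atom count.
#' @return a \code{metric_value} with no C-standard.
#' @export
enthalpic_efficiency <- function(delta_h, n_nh) {
  if (!is.numeric(n_nh) || n_nh < 1 || n_nh != round(n_nh))
    stop("n_nh must be a positive integer", call. = FALSE)
  metric_value("ENTHALPIC_EFF", -delta_h / n_nh, c_standard = NULL)
}

#' Long-format metric table for a set of compounds
#'
#' One row per compound x metric, evaluated at the context's standard
#' concentration. Metrics whose required fields are missing are skipped for
#' that compound.
#'
#' @param records list of \code{compound_record}s.
#' @param metrics character subset of c("eta_bind", "dg_per_atom", "lean",
#'   "bei", "lle").
#' @param ctx a \code{thermo_context}.
#' @return data.frame with columns id, metric, value, cstd_molar,
#'   approx.
#' @export
metric_table <- function(records,
                         metrics = c("eta_bind", "dg_per_atom", "lean",
                                     "bei", "lle"),
                         ctx = thermo_context()) {
  stopifnot(is_record_list(records))
  metrics <- match.arg(metrics, several.ok = TRUE)
  rows <- list()
  for (rec in records) for (m in metrics) {
    mv <- tryCatch(switch(m,
      eta_bind = eta_bind(rec, ctx),
      dg_per_atom = dg_per_atom(rec, ctx),
      lean = lean(rec),
      bei = bei(rec),
      lle = lle(rec)), error = function(e) NULL)
    if (is.null(mv)) next
    rows[[length(rows) + 1L]] <- data.frame(
      id = rec$id, metric = mv$metric, value = mv$value,
      cstd_molar = if (is.null(mv$c_standard)) NA_real_ else
        as_molar(mv$c_standard),
      approx = mv$approx, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
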