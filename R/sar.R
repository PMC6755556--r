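# Group efficiency over structural transformations, composite edges and
# additivity checks on substitution cycles. GE inputs are free-energy
# differences (delta_n = 0), so everything here is independent of the
# standard concentration by construction.

#' Create a structural-transformation edge
#'
#' A parent-to-child structural modification carrying the change in
#' heavy-atom count and the change in binding free energy (or p-scale
#' affinity). Differences between compounds have delta_n = 0, which is what
#' makes group efficiency independent of the standard concentration.
#'
#' @param parent_id,child_id compound identifiers.
#' @param delta_n_nh integer change in non-hydrogen atom count (may be 0,
#'   e.g. for a chiral resolution step).
#' @param ddg change in binding free energy, kcal/mol (child minus parent);
#'   either this or \code{delta_pk}.
#' @param delta_pk change in pK_D (parent-to-child affinity gain in log
#'   units); converted to kcal/mol with \code{ctx} when \code{ddg} absent.
#' @param composite flag for composite transformations (e.g. substitution
#'   plus chiral resolution).
#' @param racemate flag: the child (or parent) affinity was measured on a
#'   racemate.
#' @param ctx \code{thermo_context} used for the pK-to-energy conversion.
#' @return object of class \code{transformation_edge} with fields
#'   \code{ddg} (kcal/mol) and \code{delta_pk}.
#' @export
transformation_edge <- function(parent_id, child_id, delta_n_nh,
                                ddg = NULL, delta_pk = NULL,
                                composite = FALSE, racemate = FALSE,
                                ctx = thermo_context()) {
  if (delta_n_nh != round(delta_n_nh))
    stop("delta_n_nh must be an integer", call. = FALSE)
  if (is.null(ddg) && is.null(delta_pk))
    stop("supply ddg (kcal/mol) or delta_pk", call. = FALSE)
  if (is.null(ddg)) ddg <- -delta_pk * rtln10(ctx)
  if (is.null(delta_pk)) delta_pk <- -ddg / rtln10(ctx)
  structure(list(parent_id = as.character(parent_id),
                 child_id = as.character(child_id),
                 delta_n_nh = as.integer(delta_n_nh),
                 ddg = ddg, delta_pk = delta_pk,
                 composite = isTRUE(composite), racemate = isTRUE(racemate)),
            class = "transformation_edge")
}

#' Edge between two compound records
#'
#' Builds a \code{transformation_edge} from parent and child
#' \code{compound_record}s, taking delta_n_nh from the heavy-atom counts
#' and the free-energy difference from the affinities at the context's
#' temperature (the C-standard cancels in the difference).
#'
#' @param parent,child \code{compound_record}s.
#' @param ... passed to \code{transformation_edge}.
#' @param ctx a \code{thermo_context}.
#' @return a \code{transformation_edge}.
#' @export
edge_from_records <- function(parent, child, ..., ctx = thermo_context()) {
  stopifnot(inherits(parent, "compound_record"),
            inherits(child, "compound_record"))
  transformation_edge(parent$id, child$id,
                      delta_n_nh = child$n_nh - parent$n_nh,
                      delta_pk = child$pkd - parent$pkd, ..., ctx = ctx)
}

#' Group efficiency of a structural transformation
#'
#' \eqn{GE = -\Delta\Delta G / \Delta N_{nH}} in kcal/mol per non-hydrogen
#' atom. GE belongs to the transformation, not to the substructure added:
#' the same group can carry different GE in different structural contexts.
#' Because the free-energy difference has delta_n = 0, GE is invariant to
#' any common re-expression of the underlying affinities.
#'
#' @param edge a \code{transformation_edge} with nonzero delta_n_nh.
#' @param ctx a \code{thermo_context} (used for the optional racemate
#'   correction).
#' @param correct_racemate if TRUE and the edge is flagged racemate, add
#'   RT ln 2 to -ddg to estimate the pure-enantiomer value (assumes only
#'   one enantiomer binds); off by default.
#' @return a \code{metric_value} (metric "GE", kcal/mol per atom) tagged
#'   with the edge identity in its note.
#' @examples
#' e <- transformation_edge("7", "6", 5, ddg = -10.6 - (-5.9))
#' group_efficiency(e)$value   # 0.94
#' @export
group_efficiency <- function(edge, ctx = thermo_context(),
                             correct_racemate = FALSE) {
  stopifnot(inherits(edge, "transformation_edge"))
  if (edge$delta_n_nh == 0L)
    stop(sprintf("GE undefined for [%s -> %s]: delta_n_nh = 0",
                 edge$parent_id, edge$child_id), call. = FALSE)
  ddg <- edge$ddg
  if (correct_racemate && edge$racemate) ddg <- ddg - rt(ctx) * log(2)
  metric_value("GE", -ddg / edge$delta_n_nh, c_standard = NULL,
               temperature = ctx$temperature,
               note = sprintf("[%s -> %s]%s", edge$parent_id, edge$child_id,
                              if (edge$composite) " (composite)" else ""))
}

#' Affinity-gain slope of a transformation in log units
#'
#' \eqn{\Delta pK / \Delta N_{nH}} per non-hydrogen atom; equals
#' GE / (RT ln 10) and is invariant to the affinity unit.
#'
#' @inheritParams group_efficiency
#' @return a \code{metric_value} (metric "PK_SLOPE", log units per atom).
#' @export
pk_slope <- function(edge, ctx = thermo_context()) {
  ge <- group_efficiency(edge, ctx)
  metric_value("PK_SLOPE", ge$value / rtln10(ctx), c_standard = NULL,
               note = ge$note)
}

#' Compose a chain of transformation edges
#'
#' Sums delta_n_nh and the free-energy difference along a parent-to-child
#' chain. The composite flag is set when any member is composite or any
#' member changes affinity without changing size (delta_n_nh = 0, e.g. a
#' resolution step).
#'
#' @param path list of \code{transformation_edge}s with child of step i
#'   equal to parent of step i+1.
#' @param ctx a \code{thermo_context}.
#' @return a single \code{transformation_edge} from the first parent to the
#'   last child.
#' @export
compose_edges <- function(path, ctx = thermo_context()) {
  stopifnot(is.list(path), length(path) >= 1L)
  for (e in path) stopifnot(inherits(e, "transformation_edge"))
  if (length(path) > 1L) for (i in seq_len(length(path) - 1L))
    if (path[[i]]$child_id != path[[i + 1L]]$parent_id)
      stop(sprintf("broken chain: edge %d ends at '%s' but edge %d starts at '%s'",
                   i, path[[i]]$child_id, i + 1L, path[[i + 1L]]$parent_id),
           call. = FALSE)
  dn <- sum(vapply(path, `[[`, integer(1), "delta_n_nh"))
  ddg <- sum(vapply(path, `[[`, numeric(1), "ddg"))
  comp <- any(vapply(path, `[[`, logical(1), "composite")) ||
    (length(path) > 1L &&
       any(vapply(path, `[[`, integer(1), "delta_n_nh") == 0L))
  transformation_edge(path[[1L]]$parent_id, path[[length(path)]]$child_id,
                      dn, ddg = ddg, composite = comp,
                      racemate = any(vapply(path, `[[`, logical(1),
                                            "racemate")), ctx = ctx)
}

#' Reverse a transformation edge
#' @param edge a \code{transformation_edge}.
#' @return the child-to-parent edge with negated delta_n_nh and ddg.
#' @export
reverse_edge <- function(edge) {
  transformation_edge(edge$child_id, edge$parent_id, -edge$delta_n_nh,
                      ddg = -edge$ddg, composite = edge$composite,
                      racemate = edge$racemate)
}

#' Additivity check on a double-substitution cycle
#'
#' For compounds A, AX, AY and AXY (substituents X and Y introduced singly
#' and together), non-additivity is
#' \eqn{\Delta\Delta G[A\to AXY] - \Delta\Delta G[A\to AX] -
#' \Delta\Delta G[A\to AY]} in kcal/mol. Zero defines additive SAR;
#' positive means the combined substitution gains less than the sum of the
#' single substitutions (sub-additive). When any corner is missing the
#' verdict is indeterminate and the missing corner is named: per-group
#' free-energy contributions cannot be assigned consistently without it.
#' The value is independent of the standard concentration.
#'
#' @param a,ax,ay,axy \code{compound_record}s (any may be NULL / missing).
#' @param ctx a \code{thermo_context}.
#' @param tol additivity tolerance, kcal/mol; default 0.3 (typical assay
#'   reproducibility).
#' @return list of class \code{additivity_cycle}: \code{nonadditivity_kcal},
#'   \code{nonadditivity_pk}, \code{verdict} one of "additive",
#'   "sub-additive", "super-additive", "indeterminate", \code{missing}
#'   (names of absent corners), \code{tol}.
#' @export
additivity_check <- function(a, ax, ay, axy, ctx = thermo_context(),
                             tol = 0.3) {
  corners <- list(A = a, AX = ax, AY = ay, AXY = axy)
  missing_c <- names(corners)[vapply(corners, function(r)
    is.null(r) || !inherits(r, "compound_record"), logical(1))]
  if (length(missing_c)) {
    return(structure(list(nonadditivity_kcal = NA_real_,
                          nonadditivity_pk = NA_real_,
                          verdict = "indeterminate", missing = missing_c,
                          tol = tol), class = "additivity_cycle"))
  }
  dpk_x <- ax$pkd - a$pkd
  dpk_y <- ay$pkd - a$pkd
  dpk_xy <- axy$pkd - a$pkd
  nonadd_pk <- dpk_xy - dpk_x - dpk_y
  nonadd_kcal <- -nonadd_pk * rtln10(ctx)
  verdict <- if (abs(nonadd_kcal) <= tol) "additive"
  else if (nonadd_kcal > 0) "sub-additive" else "super-additive"
  structure(list(nonadditivity_kcal = nonadd_kcal,
                 nonadditivity_pk = nonadd_pk, verdict = verdict,
                 missing = character(0), tol = tol),
            class = "additivity_cycle")
}

#' @export
print.additivity_cycle <- function(x, ...) {
  cat("<additivity_cycle> verdict:", x$verdict, "\n")
  if (length(x$missing))
    cat("  missing corner(s):", paste(x$missing, collapse = ", "), "\n")
  else
    cat(sprintf("  nonadditivity = %.3g kcal/mol (%.3g pK units), tol %g\n",
                x$nonadditivity_kcal, x$nonadditivity_pk, x$tol))
  invisible(x)
}

#' Group efficiency of a structural prototype against an assumed zero-size
#' affinity
#'
#' Computing GE for the transformation from "nothing" to a structural
#' prototype requires assigning a free energy to a species of zero
#' molecular size, a convention with no physical basis; the result is
#' determined as much by that assumption as by the measurement. The
#' assumption is therefore a required argument, never a default, and the
#' linear dependence of the result on it (slope -1/N_nH) can be inspected
#' with \code{sweep_zero_size}.
#'
#' @param record a \code{compound_record} for the prototype.
#' @param assume_zero_size_dg assumed free energy (kcal/mol, at the
#'   context's C-standard) for the zero-molecular-size species, e.g. +4.2
#'   for a rigid-body entropy convention.
#' @param ctx a \code{thermo_context}.
#' @return a \code{metric_value} (metric "GE") whose note records the
#'   assumption.
#' @export
prototype_ge <- function(record, assume_zero_size_dg, ctx = thermo_context()) {
  if (missing(assume_zero_size_dg))
    stop("prototype GE requires an explicit zero-size affinity assumption",
         call. = FALSE)
  dg <- delta_g_from_kd(dim_quantity(record$kd_molar, 1, "M"), ctx)$value
  ddg <- dg - assume_zero_size_dg
  mv <- metric_value("GE", -ddg / record$n_nh, c_standard = ctx$c_standard,
                     temperature = ctx$temperature,
                     note = sprintf("prototype GE for '%s' assuming ΔG(MS=0) = %g kcal/mol",
                                    record$id, assume_zero_size_dg))
  mv
}

#' Sensitivity of prototype GE to the assumed zero-size affinity
#' @inheritParams prototype_ge
#' @param dg_values numeric vector of assumed zero-size free energies.
#' @return data.frame with columns assume_zero_size_dg, ge. GE is linear in
#'   the assumed zero-size free energy with slope +1/N_nH, i.e. linear in
#'   the assumed zero-size binding strength (-dG) with slope -1/N_nH: the
#'   result is determined just as much by the assumption as by the
#'   measured affinity.
#' @export
sweep_zero_size <- function(record, dg_values, ctx = thermo_context()) {
  ge <- vapply(dg_values, function(v)
    prototype_ge(record, v, ctx)$value, numeric(1))
  data.frame(assume_zero_size_dg = dg_values, ge = ge)
}
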