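# Gas constant in kcal/(mol K). The package works in kcal/mol throughout.
R_KCAL <- 1.987204e-3

# ---- exact rationals for concentration-dimension exponents ----------------
# Dimension exponents such as 1/N_nH must survive arithmetic without float
# drift, so they are stored as reduced integer fractions.

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

rational <- function(num, den = 1L) {
  if (den == 0) stop("rational with zero denominator", call. = FALSE)
  num <- as.integer(num); den <- as.integer(den)
  if (den < 0) { num <- -num; den <- -den }
  g <- gcd_int(num, den)
  if (g > 1L) { num <- num %/% g; den <- den %/% g }
  structure(list(num = num, den = den), class = "ligeff_rational")
}

rat_value <- function(r) r$num / r$den
rat_eq <- function(a, b) a$num == b$num && a$den == b$den
rat_add <- function(a, b) rational(a$num * b$den + b$num * a$den, a$den * b$den)

#' @export
format.ligeff_rational <- function(x, ...) {
  if (x$den == 1L) as.character(x$num) else paste0(x$num, "/", x$den)
}

#' @export
print.ligeff_rational <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

# ---- concentration units --------------------------------------------------

.UNIT_SCALES <- c(m = 1, mm = 1e-3, um = 1e-6, nm = 1e-9, pm = 1e-12)

#' Parse a concentration unit token
#'
#' Recognizes M, mM, uM (or the micro sign form), nM and pM,
#' case-insensitively, and returns the unit scale in molar. Unknown tokens
#' are an error, never silently treated as molar.
#'
#' @param token character unit token, e.g. "nM".
#' @return numeric scale in molar (1 = M, 1e-9 = nM, ...).
#' @examples
#' parse_conc_unit("nM")   # 1e-9
#' parse_conc_unit("uM")   # 1e-6
#' @export
parse_conc_unit <- function(token) {
  if (length(token) != 1L || is.na(token))
    stop("expected a single unit token", call. = FALSE)
  key <- tolower(trimws(token))
  key <- gsub("µ", "u", key)  # micro sign
  if (!key %in% names(.UNIT_SCALES))
    stop(sprintf("unrecognized concentration unit '%s' (expected M, mM, uM, nM or pM)",
                 token), call. = FALSE)
  unname(.UNIT_SCALES[[key]])
}

unit_name <- function(scale) {
  hit <- names(.UNIT_SCALES)[vapply(.UNIT_SCALES, function(s)
    isTRUE(all.equal(s, scale)), logical(1))]
  if (length(hit) == 1L) sub("m$", "M", hit) else paste0(scale, " M")
}

# ---- DimensionedQuantity --------------------------------------------------

#' Create a dimensioned quantity
#'
#' A numeric value carrying a concentration-dimension exponent and a unit
#' scale. Equilibrium constants of a binary complex have dimension
#' concentration^1; per-atom constants defined by K_D = k^N carry the
#' fractional dimension 1/N; pure ratios have dimension 0. The exponent is
#' stored as an exact integer fraction so that fractional dimensions survive
#' arithmetic.
#'
#' @param value numeric value in the given unit.
#' @param dim_exponent concentration-dimension exponent; a number or an
#'   object from \code{rational()}.
#' @param unit unit token ("M", "mM", "uM", "nM", "pM") or a numeric scale
#'   in molar.
#' @return an object of class \code{dim_quantity}.
#' @examples
#' kd <- dim_quantity(1, 1, "uM")
#' convert_unit(kd, "nM")   # 1000 nM
#' @export
dim_quantity <- function(value, dim_exponent = 1, unit = "M") {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (!inherits(dim_exponent, "ligeff_rational")) {
    if (dim_exponent == round(dim_exponent)) {
      dim_exponent <- rational(dim_exponent)
    } else {
      # accept 1/n for moderate n exactly
      den <- round(1 / dim_exponent)
      if (den != 0 && isTRUE(all.equal(1 / den, dim_exponent))) {
        dim_exponent <- rational(1L, den)
      } else stop("dim_exponent must be an integer, 1/n, or a rational()",
                  call. = FALSE)
    }
  }
  scale <- if (is.character(unit)) parse_conc_unit(unit) else as.numeric(unit)
  if (scale <= 0) stop("unit scale must be positive", call. = FALSE)
  structure(list(value = value, dim = dim_exponent, unit_scale = scale),
            class = "dim_quantity")
}

#' Concentration-dimension exponent of a quantity
#' @param q a \code{dim_quantity}.
#' @return numeric exponent (e.g. 1, 0, 0.1).
#' @export
dim_exponent <- function(q) rat_value(q$dim)

#' Re-express a dimensioned quantity in another unit
#'
#' The physical quantity is unchanged:
#' value_new = value_old * (scale_old/scale_new)^dim_exponent. Quantities of
#' dimension zero are invariant.
#'
#' @param q a \code{dim_quantity}.
#' @param unit target unit token or numeric scale in molar.
#' @return a \code{dim_quantity} in the new unit.
#' @export
convert_unit <- function(q, unit) {
  stopifnot(inherits(q, "dim_quantity"))
  new_scale <- if (is.character(unit)) parse_conc_unit(unit) else as.numeric(unit)
  e <- rat_value(q$dim)
  v <- q$value * (q$unit_scale / new_scale)^e
  structure(list(value = v, dim = q$dim, unit_scale = new_scale),
            class = "dim_quantity")
}

#' Value of a concentration in molar
#' @param q a \code{dim_quantity} with dimension exponent 1.
#' @return numeric value in M.
#' @export
as_molar <- function(q) {
  stopifnot(inherits(q, "dim_quantity"))
  if (!rat_eq(q$dim, rational(1L)))
    stop("as_molar requires concentration dimension 1", call. = FALSE)
  q$value * q$unit_scale
}

#' @export
format.dim_quantity <- function(x, ...) {
  e <- x$dim
  u <- unit_name(x$unit_scale)
  dimtxt <- if (e$num == 0L) "" else if (rat_eq(e, rational(1L))) u else
    paste0(u, "^", format(e))
  paste0(signif(x$value, 6), if (nzchar(dimtxt)) paste0(" ", dimtxt) else "")
}

#' @export
print.dim_quantity <- function(x, ...) {
  cat("<dim_quantity> ", format(x), "\n", sep = ""); invisible(x)
}

# ---- ThermoContext --------------------------------------------------------

#' Thermodynamic context: temperature, gas constant and standard concentration
#'
#' Binding free energies depend on the standard concentration C-standard used
#' to make the argument of the logarithm dimensionless; the context makes
#' that choice explicit everywhere.
#'
#' @param temperature kelvin; default 298.15.
#' @param c_standard standard concentration as a \code{dim_quantity} with
#'   dimension 1, a unit token, or a numeric value in molar. Default 1 M.
#' @param gas_constant kcal/(mol K); default 1.987204e-3.
#' @return an object of class \code{thermo_context}.
#' @export
thermo_context <- function(temperature = 298.15, c_standard = 1,
                           gas_constant = R_KCAL) {
  stopifnot(temperature > 0)
  cs <- as_cstd(c_standard)
  structure(list(temperature = temperature, gas_constant = gas_constant,
                 c_standard = cs), class = "thermo_context")
}

as_cstd <- function(x) {
  if (inherits(x, "dim_quantity")) {
    if (!rat_eq(x$dim, rational(1L)))
      stop("standard concentration must have dimension 1", call. = FALSE)
    return(x)
  }
  if (is.character(x)) return(dim_quantity(1, 1, x))
  dim_quantity(as.numeric(x), 1, "M")
}

#' @export
print.thermo_context <- function(x, ...) {
  cat(sprintf("<thermo_context> T = %g K, R = %g kcal/(mol K), C° = %s\n",
              x$temperature, x$gas_constant, format(x$c_standard)))
  invisible(x)
}

rt <- function(ctx) ctx$gas_constant * ctx$temperature
rtln10 <- function(ctx) rt(ctx) * log(10)

# ---- FreeEnergyTerm -------------------------------------------------------

#' Create a free-energy term tagged with its stoichiometric dimension
#'
#' A free-energy change in kcal/mol together with the change in the number
#' of species (delta_n) of its reaction and the standard concentration at
#' which its value is stated. delta_n determines how the value shifts when
#' re-expressed at another standard concentration; delta_n = 0 terms (e.g.
#' free-energy differences between compounds) are independent of it.
#'
#' @param value kcal/mol.
#' @param delta_n change in number of species (integer or \code{rational()});
#'   -1 for formation of a 1:1 complex, +1 for dissociation, 0 for a
#'   difference.
#' @param c_standard standard concentration the value refers to (unit token,
#'   molar value or \code{dim_quantity}); default 1 M.
#' @param label optional text label.
#' @return an object of class \code{energy_term}.
#' @export
energy_term <- function(value, delta_n, c_standard = 1, label = "") {
  stopifnot(is.numeric(value), length(value) == 1L)
  if (!inherits(delta_n, "ligeff_rational")) delta_n <- rational(delta_n)
  structure(list(value = value, delta_n = delta_n,
                 c_standard = as_cstd(c_standard), label = label),
            class = "energy_term")
}

#' @export
format.energy_term <- function(x, ...) {
  sprintf("%s%.4g kcal/mol [ΔN = %s] @ C° = %s",
          if (nzchar(x$label)) paste0(x$label, ": ") else "",
          x$value, format(x$delta_n), format(x$c_standard))
}

#' @export
print.energy_term <- function(x, ...) {
  cat("<energy_term> ", format(x), "\n", sep = ""); invisible(x)
}

#' Standard binding free energy from a dissociation constant
#'
#' Computes the standard free energy of binding
#' \eqn{\Delta G^\circ = RT \ln(K_D / C^\circ)} for formation of a 1:1
#' complex (delta_n = -1). A tenfold increase in C-standard decreases the
#' value by RT ln 10 (1.36 kcal/mol at 298 K).
#'
#' @param kd dissociation constant as a \code{dim_quantity} with dimension 1.
#' @param ctx a \code{thermo_context}.
#' @return an \code{energy_term} with delta_n = -1, stated at the context's
#'   standard concentration.
#' @examples
#' delta_g_from_kd(dim_quantity(1, 1, "uM"), thermo_context(298))
#' @export
delta_g_from_kd <- function(kd, ctx = thermo_context()) {
  stopifnot(inherits(kd, "dim_quantity"), inherits(ctx, "thermo_context"))
  if (!rat_eq(kd$dim, rational(1L)))
    stop("K_D must have concentration dimension 1", call. = FALSE)
  if (kd$value <= 0) stop("K_D must be positive", call. = FALSE)
  kdm <- as_molar(kd)
  cm <- as_molar(ctx$c_standard)
  energy_term(rt(ctx) * log(kdm / cm), delta_n = -1L,
              c_standard = ctx$c_standard, label = "ΔG°")
}

#' Re-express a free-energy term at a new standard concentration
#'
#' Shifts the value by \eqn{\Delta N \, RT \ln(C^\circ_{new}/C^\circ_{old})}
#' (a tenfold C-standard increase lowers a binding free energy, delta_n =
#' -1, by RT ln 10); delta_n is unchanged. Successive re-expressions
#' compose exactly, and delta_n = 0 terms are unaffected.
#'
#' @param term an \code{energy_term}.
#' @param new_c the new standard concentration (unit token, molar value, or
#'   \code{dim_quantity}).
#' @param ctx a \code{thermo_context} supplying R and T.
#' @return an \code{energy_term} stated at \code{new_c}.
#' @export
rescale_free_energy <- function(term, new_c, ctx = thermo_context()) {
  stopifnot(inherits(term, "energy_term"))
  new_c <- as_cstd(new_c)
  shift <- rat_value(term$delta_n) * rt(ctx) *
    log(as_molar(new_c) / as_molar(term$c_standard))
  energy_term(term$value + shift, term$delta_n, new_c, term$label)
}

#' Per-atom equilibrium constant with fractional dimension
#'
#' Defines k such that \eqn{K_D = k^{N_{nH}}}. The result carries the
#' fractional concentration dimension 1/N and therefore does not convert
#' between units like a plain concentration: two compounds whose k values
#' coincide numerically in one unit need not coincide in another.
#'
#' @param kd a \code{dim_quantity} with dimension 1 and positive value.
#' @param n_nh positive integer non-hydrogen atom count.
#' @return a \code{dim_quantity} with dimension 1/n_nh in the same unit
#'   as \code{kd}.
#' @examples
#' k_nh(dim_quantity(1e-3, 1, "M"), 10)   # 0.501 M^(1/10)
#' @export
k_nh <- function(kd, n_nh) {
  stopifnot(inherits(kd, "dim_quantity"))
  if (!rat_eq(kd$dim, rational(1L)))
    stop("K_D must have concentration dimension 1", call. = FALSE)
  if (kd$value <= 0) stop("K_D must be positive", call. = FALSE)
  if (!is.numeric(n_nh) || n_nh < 1 || n_nh != round(n_nh))
    stop("n_nh must be a positive integer", call. = FALSE)
  structure(list(value = kd$value^(1 / n_nh), dim = rational(1L, n_nh),
                 unit_scale = kd$unit_scale), class = "dim_quantity")
}

#' Validate a free-energy decomposition
#'
#' A sum of free-energy changes can only equal a given free-energy change
#' for every choice of standard concentration if the delta_n values of the
#' components sum to the delta_n of the total. This check is structural and
#' independent of the numeric check that the values sum to the total (after
#' re-expressing every term at a common standard concentration).
#'
#' @param total an \code{energy_term}.
#' @param components list of \code{energy_term}s.
#' @param tol numeric tolerance, kcal/mol, for the value check. Default 1e-6.
#' @param ctx a \code{thermo_context} used for re-expression.
#' @return a list of class \code{decomposition_report} with elements
#'   \code{dn_ok}, \code{value_ok}, \code{dn_total}, \code{dn_sum},
#'   \code{value_gap} (total minus component sum, at the total's
#'   C-standard).
#' @export
check_decomposition <- function(total, components, tol = 1e-6,
                                ctx = thermo_context()) {
  stopifnot(inherits(total, "energy_term"), length(components) >= 1L)
  for (cmp in components) stopifnot(inherits(cmp, "energy_term"))
  dn_sum <- Reduce(rat_add, lapply(components, `[[`, "delta_n"))
  dn_ok <- rat_eq(dn_sum, total$delta_n)
  common <- total$c_standard
  vals <- vapply(components, function(cmp)
    rescale_free_energy(cmp, common, ctx)$value, numeric(1))
  gap <- total$value - sum(vals)
  structure(list(dn_ok = dn_ok, value_ok = abs(gap) <= tol,
                 dn_total = total$delta_n, dn_sum = dn_sum,
                 value_gap = gap, tol = tol),
            class = "decomposition_report")
}

#' @export
print.decomposition_report <- function(x, ...) {
  cat("<decomposition_report>\n")
  cat(sprintf("  ΔN check:    %s (total %s vs component sum %s)\n",
              if (x$dn_ok) "PASS" else "FAIL",
              format(x$dn_total), format(x$dn_sum)))
  cat(sprintf("  value check: %s (gap %.3g kcal/mol, tol %g)\n",
              if (x$value_ok) "PASS" else "FAIL", x$value_gap, x$tol))
  invisible(x)
}
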