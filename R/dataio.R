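# CSV readers/writers with schema validation, heavy-atom counting from
# structures, and audit-trail output headers. Affinity is converted to
# molar at this boundary; everything downstream is unit-clean.

required_affinity <- function(row) {
  has_conc <- !is.na(row$affinity_value)
  has_p <- !is.na(row$p_affinity)
  list(has_conc = has_conc, has_p = has_p)
}

#' Read a compound table from CSV
#'
#' Required columns: \code{id}, \code{n_nh} (or \code{smiles}, from which
#' heavy atoms are counted), and an affinity given either as
#' \code{affinity_value} + \code{affinity_unit} or as \code{p_affinity};
#' \code{affinity_kind} must be one of KD, IC50, pKD, pIC50. Optional:
#' \code{mw}, \code{logp}, \code{hbd}, \code{hba}, \code{project_id}.
#' Lines starting with '#' are treated as header comments. Rows that fail
#' validation are reported with their line numbers and skipped; with
#' \code{strict = TRUE} any invalid row is an error. A row carrying both a
#' concentration and a p-value that disagree by more than 0.01 log units
#' gets an inconsistency warning in the report (the concentration wins).
#'
#' @param path CSV file path.
#' @param strict error on any invalid row instead of skipping it.
#' @return list with \code{records} (list of \code{compound_record}s) and
#'   \code{report} (data.frame row/field/message of validation findings).
#' @export
read_compound_table <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need_one <- c("id")
  missing_cols <- setdiff(need_one, names(df))
  if (!("n_nh" %in% names(df)) && !("smiles" %in% names(df)))
    missing_cols <- c(missing_cols, "n_nh (or smiles)")
  if (!any(c("affinity_value", "p_affinity") %in% names(df)))
    missing_cols <- c(missing_cols, "affinity_value (or p_affinity)")
  if (length(missing_cols))
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  for (col in c("n_nh", "affinity_value", "affinity_unit", "affinity_kind",
                "p_affinity", "mw", "logp", "hbd", "hba", "smiles"))
    if (is.null(df[[col]]))
      df[[col]] <- if (col %in% c("affinity_unit", "affinity_kind",
                                  "smiles")) NA_character_ else NA_real_
  records <- list()
  report <- list()
  note <- function(i, field, msg)
    report[[length(report) + 1L]] <<- data.frame(
      row = i, field = field, message = msg, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    n_nh <- row$n_nh
    if (is.na(n_nh) && !is.na(row$smiles)) {
      n_nh <- tryCatch(heavy_atom_count(row$smiles), error = function(e) {
        note(i, "smiles", conditionMessage(e)); NA_real_ })
    }
    rec <- tryCatch({
      kind <- if (is.na(row$affinity_kind)) {
        if (!is.na(row$affinity_value)) "KD" else "pKD"
      } else row$affinity_kind
      if (!kind %in% c("KD", "IC50", "pKD", "pIC50"))
        stop(sprintf("unknown affinity_kind '%s'", kind), call. = FALSE)
      if (!is.na(row$affinity_value)) {
        unit <- if (is.na(row$affinity_unit)) "M" else row$affinity_unit
        r <- compound_record(row$id, n_nh, affinity = row$affinity_value,
                             affinity_unit = unit, affinity_kind = kind,
                             mw = row$mw, logp = row$logp, hbd = row$hbd,
                             hba = row$hba)
        if (!is.na(row$p_affinity) &&
            abs(r$pkd - row$p_affinity) > 0.01)
          note(i, "p_affinity",
               sprintf("inconsistent with affinity_value by %.3g log units",
                       abs(r$pkd - row$p_affinity)))
        r
      } else {
        compound_record(row$id, n_nh, p_affinity = row$p_affinity,
                        affinity_kind = if (kind %in% c("pKD", "pIC50"))
                          kind else paste0("p", kind),
                        mw = row$mw, logp = row$logp, hbd = row$hbd,
                        hba = row$hba)
      }
    }, error = function(e) { note(i, "row", conditionMessage(e)); NULL })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(row = integer(), field = character(), message = character())
  if (strict && any(report$field == "row" | report$field == "smiles"))
    stop(sprintf("invalid rows in %s:\n%s", path,
                 paste(sprintf("  line %d [%s]: %s", report$row + 1L,
                               report$field, report$message),
                       collapse = "\n")), call. = FALSE)
  list(records = records, report = report)
}

#' Write compound records to CSV
#'
#' Emits one row per record with the affinity in molar and on the p-scale,
#' full precision. Optional audit-header lines ("# key: value") record the
#' conventions in effect; \code{read_compound_table} skips them.
#'
#' @param records list of \code{compound_record}s.
#' @param path output path.
#' @param header named character/numeric vector written as comment lines.
#' @return invisibly, the path.
#' @export
write_compound_table <- function(records, path, header = NULL) {
  stopifnot(is_record_list(records))
  df <- data.frame(
    id = vapply(records, `[[`, character(1), "id"),
    n_nh = vapply(records, `[[`, integer(1), "n_nh"),
    affinity_value = vapply(records, `[[`, numeric(1), "kd_molar"),
    affinity_unit = "M",
    affinity_kind = vapply(records, `[[`, character(1), "affinity_kind"),
    p_affinity = vapply(records, `[[`, numeric(1), "pkd"),
    mw = vapply(records, `[[`, numeric(1), "mw"),
    logp = vapply(records, `[[`, numeric(1), "logp"),
    hbd = vapply(records, `[[`, integer(1), "hbd"),
    hba = vapply(records, `[[`, integer(1), "hba"),
    stringsAsFactors = FALSE)
  # KD/IC50 rows round-trip through the concentration; p rows through pK
  df$affinity_value[df$affinity_kind %in% c("pKD", "pIC50")] <- NA_real_
  con <- file(path, "w")
  on.exit(close(con))
  write_audit_header(con, header)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

write_audit_header <- function(con, header = NULL) {
  base <- c(tool = paste0("ligeff ",
                          as.character(utils::packageVersion("ligeff"))))
  header <- c(base, header)
  writeLines(sprintf("# %s: %s", names(header),
                     vapply(header, as.character, character(1))), con)
}

audit_header <- function(ctx = thermo_context(), extra = NULL) {
  c(cstd_molar = as_molar(ctx$c_standard),
    temperature_K = ctx$temperature,
    gas_constant = ctx$gas_constant, extra)
}

#' Count non-hydrogen atoms in a structure
#'
#' Parses a SMILES string (via ChemmineR/OpenBabel) and counts atoms other
#' than hydrogen; explicit hydrogens are excluded. For an SDF file use
#' \code{heavy_atom_count_sdf}.
#'
#' @param smiles a single SMILES string.
#' @return integer heavy-atom count.
#' @examples
#' \dontrun{heavy_atom_count("c1cc[nH]n1")  # pyrazole: 5}
#' @export
heavy_atom_count <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("ChemmineR is required for structure parsing", call. = FALSE)
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e)
                    stop(sprintf("unparsable SMILES '%s': %s", smiles,
                                 conditionMessage(e)), call. = FALSE))
  count_heavy(ChemmineR::atomblock(sdf[[1]]))
}

count_heavy <- function(atomblock) {
  if (is.null(atomblock) || nrow(atomblock) == 0L)
    stop("structure has no atom block", call. = FALSE)
  elem <- sub("_[0-9]+$", "", rownames(atomblock))
  as.integer(sum(elem != "H"))
}

#' Heavy-atom counts for every record of an SDF file
#' @param path SDF (V2000) file path.
#' @return named integer vector, one count per molecule.
#' @export
heavy_atom_count_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("ChemmineR is required for structure parsing", call. = FALSE)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  counts <- vapply(seq_along(sdfs), function(i)
    count_heavy(ChemmineR::atomblock(sdfs[[i]])), integer(1))
  stats::setNames(counts, ChemmineR::sdfid(sdfs))
}

#' Read a transformation-edge table from CSV
#'
#' Columns: \code{parent_id}, \code{child_id}, and either \code{ddg_kcal}
#' or affinities resolved against a compound table via the ids; optional
#' \code{delta_n_nh} (otherwise taken from the records), \code{composite},
#' \code{racemate}.
#'
#' @param path CSV path.
#' @param records optional list of \code{compound_record}s for resolving
#'   ids.
#' @param ctx a \code{thermo_context}.
#' @return list of \code{transformation_edge}s.
#' @export
read_edge_table <- function(path, records = NULL, ctx = thermo_context()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  for (col in c("delta_n_nh", "ddg_kcal"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  for (col in c("composite", "racemate"))
    if (is.null(df[[col]])) df[[col]] <- FALSE
  byid <- if (!is.null(records))
    stats::setNames(records, vapply(records, `[[`, character(1), "id"))
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    if (!is.na(row$ddg_kcal) && !is.na(row$delta_n_nh)) {
      transformation_edge(row$parent_id, row$child_id, row$delta_n_nh,
                          ddg = row$ddg_kcal, composite = row$composite,
                          racemate = row$racemate, ctx = ctx)
    } else {
      if (is.null(byid) || is.null(byid[[row$parent_id]]) ||
          is.null(byid[[row$child_id]]))
        stop(sprintf("edge row %d: need ddg_kcal + delta_n_nh or a compound table resolving '%s' and '%s'",
                     i, row$parent_id, row$child_id), call. = FALSE)
      edge_from_records(byid[[row$parent_id]], byid[[row$child_id]],
                        composite = row$composite, racemate = row$racemate,
                        ctx = ctx)
    }
  })
}

#' Write a data.frame as CSV with an audit header
#'
#' Every output file records the tool version and the thermodynamic
#' conventions (C-standard, temperature, gas constant) in effect, as
#' comment lines; numbers are written full precision.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param ctx a \code{thermo_context}.
#' @param extra additional named header entries (e.g. seed).
#' @return invisibly, the path.
#' @export
write_report_csv <- function(df, path, ctx = thermo_context(),
                             extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  write_audit_header(con, audit_header(ctx, extra))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
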