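# Shared helpers.

# Atomic TSV write: temp file in the target directory, then rename.
.write_tsv_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  utils::write.table(x, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

# The two cohorts are never pooled in any analysis; every statistical
# operation calls this guard on its input table.
.assert_single_cohort <- function(table, expected = NULL) {
  if (!"cohort" %in% names(table)) stop("table has no 'cohort' column")
  coh <- unique(as.character(table$cohort))
  if (length(coh) != 1L)
    stop("table mixes rows from cohorts ", paste(coh, collapse = " and "),
         "; DIAN and DELCODE are analysed separately and never pooled")
  if (!is.null(expected) && coh != expected)
    stop("table is from cohort ", coh, " but ", expected, " was requested")
  invisible(coh)
}

# z-score helper used everywhere standardized coefficients are reported.
.zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a zero-variance variable")
  (x - mean(x)) / s
}

# Map a seed name ("LFC") to its connectivity column ("conn_lfc").
.conn_column <- function(seed) {
  seed <- match.arg(toupper(seed), c("LFC", "RFC", "OCC", "M1"))
  paste0("conn_", tolower(seed))
}

# Subset a cohort table to one analysis stratum.
# DIAN strata: "MC"/"NC" (group column); DELCODE: "Abeta+"/"Abeta-"
# (abeta_status column: "pos"/"neg").
.subset_stratum <- function(table, stratum, cohort) {
  if (cohort == "DIAN") {
    if (!stratum %in% c("MC", "NC"))
      stop("DIAN stratum must be 'MC' or 'NC', got '", stratum, "'")
    out <- table[table$group == stratum, , drop = FALSE]
  } else {
    if (!stratum %in% c("Abeta+", "Abeta-"))
      stop("DELCODE stratum must be 'Abeta+' or 'Abeta-', got '", stratum, "'")
    out <- table[table$abeta_status == (if (stratum == "Abeta+") "pos" else "neg"),
                 , drop = FALSE]
  }
  droplevels(out)
}
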