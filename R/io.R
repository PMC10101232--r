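# Event-table CSV dialect (NONMEM-style): columns ID, TIME, EVID (1 dose,
# 0 observation), AMT, RATE, DV and the covariates WT, PMA, PNA, GA, SCR,
# SEX; missing numeric fields written as ".".

event_table_required <- c("ID", "TIME", "EVID", "AMT", "RATE", "DV",
                          "WT", "PMA", "PNA", "GA", "SCR", "SEX")

#' Write an event table to CSV
#'
#' @param table an event table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(table, path) {
  miss <- setdiff(event_table_required, names(table))
  if (length(miss))
    stop("event table is missing column(s): ", paste(miss, collapse = ", "))
  extra <- intersect(c("DUR", "OCC", "BLQ"), names(table))
  out <- table[, c(event_table_required, extra)]
  for (nm in names(out)) {
    v <- out[[nm]]
    out[[nm]] <- ifelse(is.na(v), ".",
                        if (is.numeric(v)) format(v, digits = 17,
                                                  scientific = FALSE,
                                                  trim = TRUE)
                        else as.character(v))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event table from CSV
#'
#' Validates the documented dialect: all required columns present, "." for
#' missing values, non-negative non-decreasing times per subject, and every
#' observation preceded by at least one dose.  Validation failures report
#' the offending row and column.
#'
#' @param path CSV file path.
#' @return an `event_table` data frame.
#' @export
read_event_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  miss <- setdiff(event_table_required, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  num_cols <- setdiff(intersect(c(event_table_required, "DUR", "BLQ"),
                                names(raw)), "SEX")
  out <- raw
  for (nm in num_cols) {
    v <- raw[[nm]]
    v[v == "."] <- NA
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad))
      stop("non-numeric value in column ", nm, ", row ", bad[1])
    out[[nm]] <- parsed
  }
  for (nm in intersect(c("SEX", "OCC"), names(out)))
    out[[nm]][out[[nm]] == "."] <- NA
  out$ID <- as.integer(out$ID)
  out$EVID <- as.integer(out$EVID)
  bad <- which(!out$EVID %in% c(0L, 1L))
  if (length(bad)) stop("invalid EVID, row ", bad[1])
  bad <- which(is.na(out$TIME) | out$TIME < 0)
  if (length(bad)) stop("negative or missing TIME, row ", bad[1])
  for (id in unique(out$ID)) {
    i <- which(out$ID == id)
    if (is.unsorted(out$TIME[i]))
      stop("times not non-decreasing for subject ", id,
           " (column TIME, row ", i[which(diff(out$TIME[i]) < 0)[1] + 1], ")")
    evid <- out$EVID[i]
    first_obs <- which(evid == 0)[1]
    if (!is.na(first_obs) &&
        !any(evid[seq_len(first_obs)] == 1 &
               out$TIME[i][seq_len(first_obs)] <= out$TIME[i][first_obs]))
      stop("observation before first dose for subject ", id,
           " (column TIME, row ", i[first_obs], ")")
  }
  class(out) <- c("event_table", "data.frame")
  out
}
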