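## Delimited-table and config I/O.
##
## Conventions: tab-separated tables; '#'-prefixed comment lines carry
## units and provenance; the last '#'-prefixed line before the data is
## the column header. Configs are YAML with nested per-module sections.

#' Write a tab-separated table with '#'-prefixed header
#'
#' @param df data.frame.
#' @param file path.
#' @param comment character vector of comment lines (units, provenance);
#'   written as "# ..." above the header.
#' @export
writeTSV <- function(df, file, comment = character()) {
  con <- file(file, "w"); on.exit(close(con))
  if (length(comment)) writeLines(paste("#", comment), con)
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a table written by \code{\link{writeTSV}}
#' @param file path.
#' @return data.frame; comment lines are kept in \code{attr(x, "comments")}.
#' @export
readTSV <- function(file) {
  lines <- readLines(file)
  hdrIdx <- grep("^#", lines)
  if (!length(hdrIdx)) stop("no '#'-prefixed header line in ", file)
  hdr <- lines[hdrIdx[length(hdrIdx)]]
  cols <- strsplit(sub("^#", "", hdr), "\t", fixed = TRUE)[[1]]
  dataLines <- lines[-seq_len(hdrIdx[length(hdrIdx)])]
  dataLines <- dataLines[nzchar(dataLines)]
  if (!length(dataLines)) {
    df <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(df) <- cols
  } else {
    df <- utils::read.table(text = dataLines, sep = "\t",
                            col.names = cols, stringsAsFactors = FALSE)
  }
  attr(df, "comments") <- sub("^# ?", "",
                              lines[hdrIdx[-length(hdrIdx)]])
  df
}

.requireColumns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " table is missing column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Write / read an ITC titration table
#'
#' Columns: injection, dvi_uL, mt_uM, xt_uM, heat_kcal_per_mol. Cell
#' volume and syringe concentration travel in the comments.
#' @param exp a \linkS4class{TitrationExperiment}.
#' @param file path.
#' @export
writeITCTable <- function(exp, file) {
  df <- data.frame(injection = seq_along(exp@dvi), dvi_uL = exp@dvi,
                   mt_uM = exp@mt, xt_uM = exp@xt,
                   heat_kcal_per_mol = exp@heats)
  writeTSV(df, file, comment = c(
    sprintf("vo_uL=%.10g", exp@vo),
    sprintf("xsyringe_uM=%.10g", exp@xsyringe),
    "units: volumes uL, concentrations uM, heats kcal/mol injectant"))
}

#' @rdname writeITCTable
#' @return \code{readITCTable}: a \linkS4class{TitrationExperiment}.
#' @export
readITCTable <- function(file) {
  df <- .requireColumns(readTSV(file),
                        c("dvi_uL", "mt_uM", "xt_uM", "heat_kcal_per_mol"),
                        "ITC")
  cm <- attr(df, "comments")
  getNum <- function(key) {
    ln <- grep(paste0("^", key, "="), cm, value = TRUE)
    if (!length(ln)) stop("ITC table comments lack '", key, "='")
    as.numeric(sub(paste0("^", key, "="), "", ln[1]))
  }
  new("TitrationExperiment", vo = getNum("vo_uL"), dvi = df$dvi_uL,
      mt = df$mt_uM, xt = df$xt_uM, heats = df$heat_kcal_per_mol,
      xsyringe = getNum("xsyringe_uM"), metadata = list())
}

#' Write / read a BLI sensor-trace table (columns: time_s, signal, phase)
#' @param trace a \linkS4class{SensorTrace}.
#' @param file path.
#' @export
writeBLITable <- function(trace, file) {
  df <- data.frame(time_s = trace@time, signal = trace@signal,
                   phase = trace@phase)
  writeTSV(df, file,
           comment = "units: time s, signal sensor units (nm shift)")
}

#' @rdname writeBLITable
#' @return \code{readBLITable}: a \linkS4class{SensorTrace}.
#' @export
readBLITable <- function(file) {
  df <- .requireColumns(readTSV(file), c("time_s", "signal", "phase"),
                        "BLI")
  sensorTrace(df$time_s, df$signal, df$phase)
}

#' Write / read a CTPase phosphate table
#'
#' Columns: time_min plus phosphate_uM or od620; protein concentration
#' and any standard curve travel in the comments.
#' @param tc a \linkS4class{PhosphateTimeCourse}.
#' @param file path.
#' @export
writeCTPaseTable <- function(tc, file) {
  df <- data.frame(time_min = tc@time)
  if (length(tc@phosphate)) df$phosphate_uM <- tc@phosphate
  if (length(tc@od)) df$od620 <- tc@od
  cm <- sprintf("protein_uM=%.10g", tc@protein)
  if (is.finite(tc@curveSlope))
    cm <- c(cm, sprintf("curve_slope=%.10g", tc@curveSlope),
            sprintf("curve_intercept=%.10g", tc@curveIntercept))
  sub <- tc@metadata$substrate
  if (!is.null(sub)) cm <- c(cm, sprintf("substrate_uM=%.10g", sub))
  writeTSV(df, file, comment = c(cm, "units: time min, phosphate uM"))
}

#' @rdname writeCTPaseTable
#' @return \code{readCTPaseTable}: a \linkS4class{PhosphateTimeCourse}.
#' @export
readCTPaseTable <- function(file) {
  df <- readTSV(file)
  .requireColumns(df, "time_min", "CTPase")
  if (!("phosphate_uM" %in% names(df)) && !("od620" %in% names(df)))
    stop("CTPase table is missing column(s): phosphate_uM (or od620)")
  cm <- attr(df, "comments")
  getNum <- function(key, required = TRUE) {
    ln <- grep(paste0("^", key, "="), cm, value = TRUE)
    if (!length(ln)) {
      if (required) stop("CTPase table comments lack '", key, "='")
      return(NA_real_)
    }
    as.numeric(sub(paste0("^", key, "="), "", ln[1]))
  }
  meta <- list()
  sub <- getNum("substrate_uM", required = FALSE)
  if (is.finite(sub)) meta$substrate <- sub
  phosphateTimeCourse(
    time = df$time_min,
    phosphate = if ("phosphate_uM" %in% names(df)) df$phosphate_uM
                else numeric(),
    od = if ("od620" %in% names(df)) df$od620 else numeric(),
    curveSlope = getNum("curve_slope", required = "od620" %in% names(df)),
    curveIntercept = getNum("curve_intercept",
                            required = "od620" %in% names(df)),
    protein = getNum("protein_uM"), metadata = meta)
}

#' Read a YAML run configuration
#'
#' Nested sections per module; \code{units} declares the rate unit
#' ("per_s" or "per_min") for the \code{rates} section. Unknown top-level
#' keys are rejected.
#'
#' @param file YAML path.
#' @param allowed allowed top-level keys.
#' @return named list.
#' @export
readRunConfig <- function(file,
                          allowed = c("command", "rates", "totals", "units",
                                      "seed", "outdir", "log_level",
                                      "network", "spreading", "generator",
                                      "fit")) {
  cfg <- yaml::read_yaml(file)
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg
}

#' Write the resolved configuration next to run outputs
#' @param cfg named list.
#' @param outDir output directory.
#' @export
writeRunConfig <- function(cfg, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(outDir, "resolved-config.yaml"))
  invisible(file.path(outDir, "resolved-config.yaml"))
}

.rateSetFromConfig <- function(cfg) {
  r <- cfg$rates
  if (is.null(r)) stop("config lacks a 'rates' section")
  need <- c("kOC", "kCO", "kOCdna", "kCOdna", "kH", "kdOpen")
  missing <- setdiff(need, names(r))
  if (length(missing))
    stop("rates section is missing: ", paste(missing, collapse = ", "))
  units <- if (!is.null(cfg$units$rates)) cfg$units$rates else "per_s"
  if (!units %in% c("per_s", "per_min"))
    stop("units.rates must be 'per_s' or 'per_min', got '", units, "'")
  rateSet(kOC = r$kOC, kCO = r$kCO, kOCdna = r$kOCdna, kCOdna = r$kCOdna,
          kH = r$kH, kdOpen = r$kdOpen,
          kOn = if (is.null(r$kOn)) NA_real_ else r$kOn,
          units = units)
}
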