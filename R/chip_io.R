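#' @importFrom stats dnorm lm.fit median quantile rnorm runif sd setNames var
#' @importFrom utils read.delim write.table
NULL

PROBE_LEN <- 25L
BASES <- c("A", "C", "G", "T")

grid_key <- function(x, y, n_cols) as.numeric(y) * n_cols + as.numeric(x)

#' Assemble probe annotation and intensities into a chip object
#'
#' A `chip_data` object bundles the probe annotation table (probe set
#' membership, grid coordinates, 25-mer sequence, PM/MM role) with the raw
#' per-cell intensities of one hybridization. It is the common currency of
#' all downstream operations (background correction, sensitivity fitting,
#' NN+GGG calibration).
#'
#' @param probes data.frame with columns `probe_set_id`, `x`, `y`,
#'   `sequence`, and optionally `role` (`"PM"`/`"MM"`) and `pair_id`.
#' @param intensities data.frame with columns `x`, `y`, `intensity`.
#' @param n_cols,n_rows grid dimensions; defaults to the tight bounding box.
#' @return object of class `chip_data`.
#' @export
chip_data <- function(probes, intensities, n_cols = NULL, n_rows = NULL) {
  stopifnot(is.data.frame(probes), is.data.frame(intensities))
  probes <- validate_probes(probes)
  need <- c("x", "y", "intensity")
  if (!all(need %in% names(intensities)))
    stop("intensities must have columns x, y, intensity")
  if (any(intensities$intensity < 0)) stop("negative intensity values")
  if (is.null(n_cols)) n_cols <- max(probes$x, intensities$x) + 1L
  if (is.null(n_rows)) n_rows <- max(probes$y, intensities$y) + 1L
  if (any(probes$x >= n_cols | probes$y >= n_rows))
    stop("probe coordinates outside the chip grid")
  key <- grid_key(intensities$x, intensities$y, n_cols)
  if (anyDuplicated(key)) stop("duplicate (x, y) in intensities")
  structure(
    list(probes = probes, intensities = intensities,
         n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)),
    class = "chip_data")
}

validate_probes <- function(probes) {
  need <- c("probe_set_id", "x", "y", "sequence")
  if (!all(need %in% names(probes)))
    stop("probe table must have columns probe_set_id, x, y, sequence")
  probes$sequence <- toupper(probes$sequence)
  bad_len <- which(nchar(probes$sequence) != PROBE_LEN)
  if (length(bad_len))
    stop("row ", bad_len[1], ": sequence length ",
         nchar(probes$sequence[bad_len[1]]), " != ", PROBE_LEN)
  bad_chr <- grep(sprintf("[^%s]", paste(BASES, collapse = "")), probes$sequence)
  if (length(bad_chr))
    stop("row ", bad_chr[1], ": sequence contains non-ACGT characters")
  if (is.null(probes$role)) probes$role <- "PM"
  if (!all(probes$role %in% c("PM", "MM"))) stop("role must be PM or MM")
  if (is.null(probes$pair_id)) probes$pair_id <- NA_character_
  if (anyDuplicated(probes[c("x", "y")])) stop("duplicate (x, y) among probes")
  probes$x <- as.integer(probes$x)
  probes$y <- as.integer(probes$y)
  probes
}

#' @export
print.chip_data <- function(x, ...) {
  cat(sprintf("chip_data: %d probes in %d probe sets; grid %d x %d; %d intensities\n",
              nrow(x$probes), length(unique(x$probes$probe_set_id)),
              x$n_cols, x$n_rows, nrow(x$intensities)))
  invisible(x)
}

#' Per-probe intensities of a chip
#'
#' Looks up the intensity of every probe by its grid coordinate.
#'
#' @param chip a `chip_data` object.
#' @return numeric vector aligned with `chip$probes` rows (NA where missing).
#' @export
probe_intensities <- function(chip) {
  ikey <- grid_key(chip$intensities$x, chip$intensities$y, chip$n_cols)
  pkey <- grid_key(chip$probes$x, chip$probes$y, chip$n_cols)
  chip$intensities$intensity[match(pkey, ikey)]
}

#' Read a probe annotation table
#'
#' Supports the Affymetrix probe-tab dialect (tab-separated, header columns
#' `Probe Set Name`, `Probe X`, `Probe Y`, `Probe Sequence`) and a plain TSV
#' with columns `probe_set_id`, `x`, `y`, `sequence` and optionally `role`.
#'
#' @param path file path.
#' @param dialect `"affy_tab"` or `"tsv"`.
#' @return data.frame of probe records (sequences upper-cased; role `PM`
#'   unless an explicit role column is present).
#' @export
read_probe_table <- function(path, dialect = c("affy_tab", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "affy_tab") {
    pick <- function(pats) {
      hit <- which(Reduce(`|`, lapply(pats, grepl, x = tolower(names(tab)))))
      if (!length(hit)) stop("probe-tab header lacks a column matching: ",
                             paste(pats, collapse = "/"))
      hit[1]
    }
    out <- data.frame(
      probe_set_id = as.character(tab[[pick("probe set")]]),
      x = tab[[pick("probe x")]],
      y = tab[[pick("probe y")]],
      sequence = as.character(tab[[pick("sequence")]]),
      stringsAsFactors = FALSE)
    role_col <- grep("interrogation|role|type", tolower(names(tab)))
    if (length(role_col) && all(tab[[role_col[1]]] %in% c("PM", "MM")))
      out$role <- tab[[role_col[1]]]
  } else {
    need <- c("probe_set_id", "x", "y", "sequence")
    if (!all(need %in% names(tab)))
      stop("tsv probe table needs columns: ", paste(need, collapse = ", "))
    out <- tab[intersect(c(need, "role", "pair_id"), names(tab))]
  }
  validate_probes(out)
}

#' Write a probe annotation table
#'
#' @param probes data.frame of probe records.
#' @param path output path.
#' @param dialect `"affy_tab"` or `"tsv"`.
#' @export
write_probe_table <- function(probes, path, dialect = c("affy_tab", "tsv")) {
  dialect <- match.arg(dialect)
  probes <- validate_probes(probes)
  if (dialect == "affy_tab") {
    out <- data.frame(`Probe Set Name` = probes$probe_set_id,
                      `Probe X` = probes$x, `Probe Y` = probes$y,
                      `Probe Sequence` = probes$sequence,
                      Role = probes$role, check.names = FALSE)
  } else {
    out <- probes[c("probe_set_id", "x", "y", "sequence", "role")]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read probe intensities
#'
#' Reads either an ASCII CEL file (version-3 text dialect with `[CEL]`,
#' `[HEADER]` and `[INTENSITY]` sections; the `MEAN` column is taken as the
#' probe intensity) or a plain TSV with columns `x`, `y`, `intensity`.
#' Binary CEL files (v4/AGCC) are rejected.
#'
#' @param path file path.
#' @param format `"cel_ascii"` or `"tsv"`.
#' @return list with `intensities` (data.frame x, y, intensity) and
#'   `n_cols`, `n_rows`.
#' @export
read_intensities <- function(path, format = c("cel_ascii", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("x", "y", "intensity") %in% names(tab)))
      stop("tsv intensity file needs columns x, y, intensity")
    if (any(tab$intensity < 0)) stop("negative intensity values")
    return(list(intensities = tab[c("x", "y", "intensity")],
                n_cols = max(tab$x) + 1L, n_rows = max(tab$y) + 1L))
  }
  raw <- readBin(path, "raw", n = 64L)
  if (any(raw == as.raw(0L)))
    stop("binary CEL file detected; only the ASCII (version 3) dialect is supported")
  lines <- readLines(path, warn = FALSE)
  sect <- function(name) {
    i <- match(paste0("[", name, "]"), trimws(lines))
    if (is.na(i)) stop("missing [", name, "] section in CEL file")
    i
  }
  sect("CEL")
  h0 <- sect("HEADER")
  field <- function(key) {
    ln <- grep(paste0("^", key, "="), lines[(h0 + 1):length(lines)], value = TRUE)
    if (!length(ln)) stop("missing ", key, " in CEL [HEADER]")
    as.integer(sub(paste0("^", key, "="), "", ln[1]))
  }
  n_cols <- field("Cols")
  n_rows <- field("Rows")
  i0 <- sect("INTENSITY")
  nline <- grep("^NumberCells=", lines[(i0 + 1):length(lines)])
  if (!length(nline)) stop("missing NumberCells in CEL [INTENSITY]")
  n_cells <- as.integer(sub("^NumberCells=", "", lines[i0 + nline[1]]))
  hline <- grep("^CellHeader=", lines[(i0 + 1):length(lines)])[1]
  if (is.na(hline)) stop("missing CellHeader in CEL [INTENSITY]")
  start <- i0 + hline + 1L
  body <- lines[start:length(lines)]
  stopat <- grep("^\\s*$|^\\[", body)
  if (length(stopat)) body <- body[seq_len(stopat[1] - 1L)]
  if (length(body) != n_cells)
    stop("CEL [INTENSITY] declares ", n_cells, " cells but has ",
         length(body), " data rows")
  mat <- matrix(scan(text = body, quiet = TRUE), nrow = n_cells, byrow = TRUE)
  out <- data.frame(x = as.integer(mat[, 1]), y = as.integer(mat[, 2]),
                    intensity = mat[, 3])
  if (any(out$intensity < 0)) stop("negative intensity values in CEL file")
  list(intensities = out, n_cols = n_cols, n_rows = n_rows)
}

#' Write probe intensities
#'
#' Writes the intensity map of a chip as an ASCII CEL (version 3) file or
#' plain TSV. The output round-trips through [read_intensities()] to at
#' least 6 significant digits, and the CEL header carries the chip grid
#' dimensions so corrected chips keep their geometry.
#'
#' @param chip a `chip_data` object with a complete intensity map.
#' @param path output path.
#' @param format `"cel_ascii"` or `"tsv"`.
#' @export
write_intensities <- function(chip, path, format = c("cel_ascii", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(chip, "chip_data"))
  ints <- chip$intensities
  if (nrow(ints) == 0) stop("chip has no intensities to write")
  if (format == "tsv") {
    write.table(data.frame(x = ints$x, y = ints$y,
                           intensity = signif(ints$intensity, 8)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "[CEL]", "Version=3", "",
    "[HEADER]",
    paste0("Cols=", chip$n_cols), paste0("Rows=", chip$n_rows),
    paste0("TotalX=", chip$n_cols), paste0("TotalY=", chip$n_rows),
    "OffsetX=0", "OffsetY=0", "Algorithm=gstackr", "",
    "[INTENSITY]",
    paste0("NumberCells=", nrow(ints)),
    "CellHeader=X\tY\tMEAN\tSTDV\tNPIXELS"), con)
  writeLines(sprintf("%3d\t%3d\t%s\t%.1f\t%3d", ints$x, ints$y,
                     formatC(ints$intensity, digits = 8, format = "g"),
                     0, 25L), con)
  invisible(path)
}

#' Pair perfect-match probes with their mismatch partners
#'
#' On GeneChip layouts each PM probe at grid position (x, y) is paired with
#' the MM probe directly below it at (x, y + 1). The MM sequence equals the
#' PM sequence except at the middle base (position 13), which carries the
#' Watson-Crick complement. When explicit roles are present they are used;
#' otherwise the layout convention decides who is PM.
#'
#' @param probes data.frame of probe records.
#' @return data.frame with one row per pair: `pm_idx`, `mm_idx` (row indices
#'   into `probes`), `probe_set_id`.
#' @export
pair_pm_mm <- function(probes) {
  probes <- validate_probes(probes)
  mid <- 13L
  flank <- function(s) paste0(substr(s, 1, mid - 1), substr(s, mid + 1, PROBE_LEN))
  has_roles <- any(probes$role == "MM")
  key <- grid_key(probes$x, probes$y, max(probes$x) + 1L)
  if (has_roles) {
    pm <- which(probes$role == "PM")
    mm <- which(probes$role == "MM")
    mm_of <- match(grid_key(probes$x[pm], probes$y[pm] + 1L,
                            max(probes$x) + 1L), key[mm])
    pm_idx <- pm[!is.na(mm_of)]
    mm_idx <- mm[mm_of[!is.na(mm_of)]]
  } else {
    # layout convention only: a row is a PM iff the cell below holds a probe
    # of the same probe set with identical flanking sequence
    cand_pm <- seq_len(nrow(probes))
    below <- match(grid_key(probes$x, probes$y + 1L, max(probes$x) + 1L), key)
    ok <- !is.na(below) &
      probes$probe_set_id == probes$probe_set_id[ifelse(is.na(below), 1L, below)] &
      flank(probes$sequence) ==
        flank(probes$sequence[ifelse(is.na(below), 1L, below)])
    pm_idx <- cand_pm[ok]
    mm_idx <- below[ok]
    # a probe may not serve as both PM and somebody's MM
    drop <- pm_idx %in% mm_idx
    pm_idx <- pm_idx[!drop]; mm_idx <- mm_idx[!drop]
  }
  if (!length(pm_idx)) stop("no PM/MM pairs found")
  s_pm <- probes$sequence[pm_idx]
  s_mm <- probes$sequence[mm_idx]
  comp <- chartr("ACGT", "TGCA", substr(s_pm, mid, mid))
  bad_mid <- substr(s_mm, mid, mid) != comp
  bad_flank <- flank(s_pm) != flank(s_mm)
  if (any(bad_mid | bad_flank))
    stop("PM/MM pair sequence mismatch: MM must equal PM except for the ",
         "complemented middle base at position ", mid,
         " (first offending PM row: ", pm_idx[which(bad_mid | bad_flank)[1]], ")")
  data.frame(pm_idx = pm_idx, mm_idx = mm_idx,
             probe_set_id = probes$probe_set_id[pm_idx],
             stringsAsFactors = FALSE)
}
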