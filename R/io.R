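# File formats. Curves travel as two-column CSV with a commented metadata
# header; no public standard exists for field-cycling relaxometer exports,
# so a documented Stelar-like stanza dialect is also supported behind the
# same relax_acquisition contract.

fmt_num <- function(x) sprintf("%.17g", x)

# metadata keys promoted to typed acquisition fields
.curve_fields <- c("field_mhz", "sequence_type", "temperature_c")

#' Write / read a relaxation curve file
#'
#' The curve format is CSV with columns `tau_s`, `signal`, preceded by
#' comment lines `# key: value` carrying the acquisition metadata
#' (`field_mhz`, `sequence_type`, `temperature_c`, plus any scalar labels
#' from `meta`). Values are written with 17 significant digits, so a write
#' / read round trip is lossless to double precision. Malformed rows are
#' reported with their line number.
#'
#' @param acq A [relax_acquisition()].
#' @param path File path.
#' @return `write_curve()` returns `path` invisibly; `read_curve()` returns
#'   a [relax_acquisition()].
#' @export
write_curve <- function(acq, path) {
  stopifnot(inherits(acq, "relax_acquisition"))
  hdr <- c(sprintf("# field_mhz: %s", fmt_num(acq$field_mhz)),
           sprintf("# sequence_type: %s", acq$sequence_type),
           sprintf("# temperature_c: %s", fmt_num(acq$temperature_c)))
  flat <- acq$meta[vapply(acq$meta, function(v)
    is.atomic(v) && length(v) == 1L, logical(1))]
  for (nm in names(flat)) {
    v <- flat[[nm]]
    hdr <- c(hdr, sprintf("# %s: %s",
                          nm, if (is.numeric(v)) fmt_num(v) else as.character(v)))
  }
  body <- paste(fmt_num(acq$tau_s), fmt_num(acq$signal), sep = ",")
  writeLines(c(hdr, "tau_s,signal", body), path)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  meta <- list()
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(m[2])]] <- if (!is.na(num)) num else val
    }
  }
  data_lines <- which(!is_comment & nzchar(trimws(lines)))
  if (!length(data_lines)) stop("no data in ", path, call. = FALSE)
  hdr_line <- data_lines[1]
  cols <- trimws(strsplit(lines[hdr_line], ",")[[1]])
  if (!all(c("tau_s", "signal") %in% cols)) {
    stop(sprintf("%s line %d: expected columns tau_s,signal", path, hdr_line),
         call. = FALSE)
  }
  rows <- data_lines[-1]
  tau <- signal <- numeric(length(rows))
  for (k in seq_along(rows)) {
    ln <- rows[k]
    parts <- strsplit(lines[ln], ",")[[1]]
    if (length(parts) < length(cols)) {
      stop(sprintf("%s line %d: malformed row '%s'", path, ln, lines[ln]),
           call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(parts))
    t_k <- vals[match("tau_s", cols)]
    s_k <- vals[match("signal", cols)]
    if (!is.finite(t_k) || !is.finite(s_k)) {
      stop(sprintf("%s line %d: non-numeric or NaN value in '%s'",
                   path, ln, lines[ln]), call. = FALSE)
    }
    if (t_k < 0) {
      stop(sprintf("%s line %d: negative tau %g", path, ln, t_k),
           call. = FALSE)
    }
    tau[k] <- t_k
    signal[k] <- s_k
  }
  if (any(diff(tau) <= 0)) {
    bad <- rows[which(diff(tau) <= 0)[1] + 1L]
    stop(sprintf("%s line %d: tau values not strictly increasing", path, bad),
         call. = FALSE)
  }
  field <- meta[["field_mhz"]] %||% NA_real_
  seqt <- meta[["sequence_type"]] %||% "IR"
  temp <- meta[["temperature_c"]] %||% NA_real_
  meta[.curve_fields] <- NULL
  relax_acquisition(tau, signal,
                    field_mhz = as.numeric(field),
                    sequence_type = as.character(seqt),
                    temperature_c = as.numeric(temp), meta = meta)
}

#' Write / read a Matrigel extracellular-rate table
#'
#' Plain two-column CSV (`field_mhz`, `r1_ex`).
#'
#' @param table Data frame with columns `field_mhz`, `r1_ex`.
#' @param path File path.
#' @export
write_matrigel <- function(table, path) {
  table <- validate_matrigel(table)
  writeLines(c("field_mhz,r1_ex",
               paste(fmt_num(table$field_mhz), fmt_num(table$r1_ex),
                     sep = ",")), path)
  invisible(path)
}

#' @rdname write_matrigel
#' @export
read_matrigel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  validate_matrigel(read.csv(path))
}

#' Write / read a multi-field dataset directory
#'
#' One curve CSV per field (`curve_<field>MHz.csv`), `matrigel.csv`, and a
#' `dataset.json` carrying tissue class and metadata. A write / read round
#' trip reproduces the dataset losslessly.
#'
#' @param ds An [nmrd_dataset()].
#' @param dir Directory (created if needed).
#' @export
write_nmrd_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "nmrd_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(ds$acquisitions))
  for (i in seq_along(ds$acquisitions)) {
    a <- ds$acquisitions[[i]]
    files[i] <- sprintf("curve_%06.4fMHz.csv", a$field_mhz)
    write_curve(a, file.path(dir, files[i]))
  }
  write_matrigel(ds$matrigel, file.path(dir, "matrigel.csv"))
  jsonlite::write_json(
    list(tissue_class = ds$tissue_class, curves = files, meta = ds$meta),
    file.path(dir, "dataset.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' @rdname write_nmrd_dataset
#' @export
read_nmrd_dataset <- function(dir) {
  cfg_path <- file.path(dir, "dataset.json")
  if (!file.exists(cfg_path)) {
    stop("no dataset.json in ", dir, call. = FALSE)
  }
  cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  acqs <- lapply(cfg$curves, function(f) read_curve(file.path(dir, f)))
  nmrd_dataset(acqs, read_matrigel(file.path(dir, "matrigel.csv")),
               tissue_class = cfg$tissue_class,
               meta = if (is.null(cfg$meta)) list() else cfg$meta)
}

#' Read a Stelar-like relaxometer export
#'
#' Parses a simple stanza-per-field text dump of the kind fast
#' field-cycling relaxometers emit. The dialect implemented here is
#' documented, NOT authoritative (vendor layouts vary by firmware):
#' each stanza is
#' \preformatted{
#' SEQUENCE: PP/S          # or NP/S, IR
#' BRLX: 0.01 MHz          # relaxation field
#' TEMP: 25 C              # optional
#' DATA:
#' <tau_s>  <signal>       # whitespace-separated, one pair per line
#' ...
#' }
#' with stanzas separated by blank lines.
#'
#' @param path File path.
#' @return List of [relax_acquisition()] objects, one per stanza.
#' @export
read_stelar <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(c(TRUE, blank[-length(blank)])) * !blank
  out <- list()
  for (g in setdiff(unique(grp), 0)) {
    stanza <- lines[grp == g]
    get_key <- function(key) {
      ln <- grep(paste0("^\\s*", key, "\\s*:"), stanza, value = TRUE)
      if (!length(ln)) return(NA_character_)
      trimws(sub(paste0("^\\s*", key, "\\s*:"), "", ln[1]))
    }
    seq_raw <- get_key("SEQUENCE")
    seqt <- if (is.na(seq_raw)) "PP"
            else if (grepl("^NP", seq_raw)) "NP"
            else if (grepl("^IR", seq_raw)) "IR" else "PP"
    brlx <- suppressWarnings(as.numeric(sub("\\s*MHz\\s*$", "",
                                            get_key("BRLX"))))
    temp <- suppressWarnings(as.numeric(sub("\\s*C\\s*$", "",
                                            get_key("TEMP"))))
    data_at <- grep("^\\s*DATA\\s*:", stanza)
    if (!length(data_at)) {
      stop("stanza without DATA section in ", path, call. = FALSE)
    }
    rows <- stanza[(data_at[1] + 1):length(stanza)]
    rows <- rows[nzchar(trimws(rows))]
    mat <- do.call(rbind, lapply(rows, function(r) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(r), "\\s+")[[1]]))
      if (length(v) < 2L || any(!is.finite(v[1:2]))) {
        stop("malformed data row in ", path, ": '", r, "'", call. = FALSE)
      }
      v[1:2]
    }))
    out[[length(out) + 1L]] <- relax_acquisition(
      mat[, 1], mat[, 2], field_mhz = brlx, sequence_type = seqt,
      temperature_c = temp)
  }
  out
}

#' Write acquisitions in the Stelar-like stanza dialect
#'
#' Companion writer for [read_stelar()] (round-trip tested); mainly useful
#' for generating test fixtures in the vendor-like layout.
#'
#' @param acqs List of [relax_acquisition()] objects.
#' @param path File path.
#' @export
write_stelar <- function(acqs, path) {
  chunks <- lapply(acqs, function(a) {
    c(sprintf("SEQUENCE: %s", switch(a$sequence_type, NP = "NP/S",
                                     PP = "PP/S", "IR")),
      sprintf("BRLX: %s MHz", fmt_num(a$field_mhz)),
      if (is.finite(a$temperature_c))
        sprintf("TEMP: %s C", fmt_num(a$temperature_c)),
      "DATA:",
      paste(fmt_num(a$tau_s), fmt_num(a$signal), sep = "  "),
      "")
  })
  writeLines(unlist(chunks), path)
  invisible(path)
}
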