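#' Write a volume as an ASCII-encoded NRRD file
#'
#' Plain-text NRRD (encoding: ascii) with voxel spacing, origin, the
#' quantity tag and reconstruction provenance as key-value fields. ASCII
#' encoding keeps the artifacts grep-able and portable at the cost of size;
#' use it for slices and desk-scale volumes.
#'
#' @param v A `ct_volume`.
#' @param path Output file path (conventionally `.nrrd`).
#' @return `path`, invisibly.
#' @export
write_volume_nrrd <- function(v, path) {
  stopifnot(inherits(v, "ct_volume"))
  d <- dim(v$values)
  nd <- length(d)
  sp <- c(v$voxel_size, v$voxel_size,
          if (nd == 3) v$z_spacing else NULL)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "NRRD0004",
    "# decbct reconstructed volume",
    "type: double",
    paste0("dimension: ", nd),
    paste0("sizes: ", paste(d, collapse = " ")),
    paste0("spacings: ", paste(sp[seq_len(nd)], collapse = " ")),
    "encoding: ascii",
    paste0("space origin: (",
           paste(v$origin[seq_len(nd)], collapse = ","), ")"),
    paste0("quantity:=", v$quantity),
    paste0("provenance:=", v$provenance),
    ""), con)
  writeLines(paste(format(as.vector(v$values), digits = 17, trim = TRUE),
                   collapse = " "), con)
  invisible(path)
}

#' Read a volume written by [write_volume_nrrd()]
#'
#' Minimal reader for the ASCII NRRD subset this package writes.
#'
#' @param path File path.
#' @return A `ct_volume`.
#' @export
read_volume_nrrd <- function(path) {
  lines <- readLines(path)
  blank <- which(lines == "")[1]
  hdr <- lines[seq_len(blank - 1)]
  get_field <- function(key) {
    ln <- grep(paste0("^", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^", key, ":=?\\s*"), "", ln[1])
  }
  if (!identical(get_field("encoding"), "ascii")) {
    stop("only ascii-encoded NRRD files are supported", call. = FALSE)
  }
  sizes <- as.integer(strsplit(get_field("sizes"), "\\s+")[[1]])
  spacings <- as.numeric(strsplit(get_field("spacings"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(gsub("[()]", "", get_field("space origin")),
                                ",")[[1]])
  vals <- as.numeric(strsplit(paste(lines[(blank + 1):length(lines)],
                                    collapse = " "), "\\s+")[[1]])
  vals <- vals[!is.na(vals)]
  stopifnot(length(vals) == prod(sizes))
  values <- if (length(sizes) == 2) {
    matrix(vals, sizes[1], sizes[2])
  } else {
    array(vals, sizes)
  }
  structure(list(values = values, voxel_size = spacings[1],
                 z_spacing = if (length(spacings) >= 3) spacings[3]
                             else spacings[1],
                 origin = c(origin, 0)[1:3],
                 quantity = get_field("quantity") %||% "unknown",
                 provenance = get_field("provenance") %||% ""),
            class = "ct_volume")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load pipeline artifacts
#'
#' Projection sets, basis projections and look-up tables are cached and
#' exchanged as RDS files (self-describing R serialisation).
#'
#' @param x Object to save.
#' @param path File path.
#' @return `path` (save) or the restored object (load).
#' @export
save_artifact <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname save_artifact
#' @export
load_artifact <- function(path) readRDS(path)

#' Write an evaluation report as CSV
#'
#' @param report A `de_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  df <- as.data.frame(report)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
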