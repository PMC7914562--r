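#' Write a decay stack as multi-page TIFF plus JSON sidecar
#'
#' One TIFF page per time bin. Counts up to 65535 are stored as exact
#' 16-bit integers; larger counts fall back to scaled 32-bit float pages
#' (exact for counts below 2^24), with the integer scale recorded in the
#' sidecar. The sidecar (same path, `.json` extension) carries the
#' instrument configuration and, when present, the ground-truth phantom,
#' so the canonical on-disk format is fully self-describing and
#' plain-text inspectable.
#'
#' @param stack A `decay_stack`.
#' @param path Output TIFF path (`.tiff`/`.tif`); the sidecar replaces
#'   the extension with `.json`.
#' @return Invisibly, the two paths written.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "decay_stack"))
  counts <- stack$counts
  maxc <- max(counts)
  if (maxc <= 65535) {
    dtype <- "uint16"; scale <- 65535
    bits <- 16L
  } else {
    dtype <- "float32"; scale <- maxc
    bits <- 32L
  }
  pages <- lapply(seq_len(dim(counts)[3]),
                  function(k) counts[, , k] / scale)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits,
                            compression = "none"), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write TIFF at ", path)
  sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  meta <- list(
    format = "fiberhdim-stack", format_version = 1L,
    dim = dim(counts), dtype = dtype, scale = scale,
    config = unclass(stack$config),
    truth = if (!is.null(stack$truth)) serialize_phantom(stack$truth)
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), sidecar)
  invisible(c(tiff = path, json = sidecar))
}

serialize_phantom <- function(phantom) {
  list(
    label_image = phantom$label_image,
    brightness = as.list(phantom$brightness),
    cell_mixtures = lapply(phantom$cell_mixtures, function(mix)
      lapply(mix, function(e)
        c(unclass(e$species)[c("name", "lifetimes", "amplitudes",
                               "emission_peak", "emission_width",
                               "r0", "r_inf", "theta_rot", "r_max")],
          list(fraction = e$fraction))))
  )
}

deserialize_phantom <- function(x) {
  mixtures <- lapply(x$cell_mixtures, function(mix)
    lapply(mix, function(e) {
      fr <- e$fraction
      e$fraction <- NULL
      list(species = do.call(fluor_species, e), fraction = fr)
    }))
  lab <- x$label_image
  if (!is.matrix(lab)) lab <- do.call(rbind, lapply(lab, unlist))
  scene_phantom(lab, mixtures, unlist(x$brightness))
}

#' Read a decay stack (TIFF + JSON sidecar, or SDT)
#'
#' The format is chosen by extension: `.tif`/`.tiff` expects the sidecar
#' written by [write_stack()]; `.sdt` dispatches to [read_sdt()]. TIFF
#' page counts are checked against the sidecar's bin count.
#'
#' @param path File path.
#' @return A `decay_stack`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.sdt$", path, ignore.case = TRUE)) return(read_sdt(path))
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("unsupported stack format: ", basename(path))
  sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::fromJSON(readLines(sidecar), simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = (meta$dtype == "uint16"))
  if (length(pages) != meta$dim[3])
    stop("TIFF has ", length(pages), " pages but sidecar says ",
         meta$dim[3], " time bins")
  counts <- array(0, dim = meta$dim)
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    counts[, , k] <- if (meta$dtype == "uint16") pg else round(pg * meta$scale)
  }
  cfg_fields <- meta$config
  cfg <- do.call(instrument_config, cfg_fields)
  truth <- if (!is.null(meta$truth)) deserialize_phantom(meta$truth)
  structure(list(counts = counts, config = cfg, truth = truth),
            class = "decay_stack")
}

# --- Becker & Hickl SDT (read-only, documented subset) ----------------------

# 42-byte SDT file header field layout (little-endian):
#   int16 revision; int32 info_offs; int16 info_length; int32 setup_offs;
#   int16 setup_length; int32 data_block_offs; int16 no_of_data_blocks;
#   int32 data_block_length; int32 meas_desc_block_offs;
#   int16 no_of_meas_desc_blocks; int16 meas_desc_block_length;
#   uint16 header_valid; uint32 reserved1; uint16 reserved2; uint16 chksum
# Measurement-description subset read by this package (offsets within the
# block): int32 scan_x @0; int32 scan_y @4; int32 adc_re @8;
# float32 tac_range (s) @12; int32 tac_gain @16.
# Data block header (22 bytes): int16 block_no; int32 data_offs;
# int32 next_block_offs; uint16 block_type; int16 meas_desc_block_no;
# uint32 lblock_no; uint32 block_length.  Only block_type 1
# (uncompressed uint16 counts, time channel fastest, then x, then y) is
# supported; anything else fails loudly naming the block type.

read_sdt_header <- function(con) {
  r <- function(what, size, signed = TRUE)
    readBin(con, what, 1, size = size, signed = signed, endian = "little")
  list(revision = r(integer(), 2),
       info_offs = r(integer(), 4), info_length = r(integer(), 2),
       setup_offs = r(integer(), 4), setup_length = r(integer(), 2),
       data_block_offs = r(integer(), 4), no_of_data_blocks = r(integer(), 2),
       data_block_length = r(integer(), 4),
       meas_desc_block_offs = r(integer(), 4),
       no_of_meas_desc_blocks = r(integer(), 2),
       meas_desc_block_length = r(integer(), 2),
       header_valid = r(integer(), 2, signed = FALSE),
       reserved1 = r(integer(), 4), reserved2 = r(integer(), 2),
       chksum = r(integer(), 2))
}

#' Read a Becker & Hickl SDT file
#'
#' Read-only support for the publicly documented SDT layout subset: the
#' 42-byte file header, one measurement description block (image size,
#' ADC resolution, TAC range), and a single uncompressed 16-bit data
#' block holding one decay curve per pixel. Compressed or otherwise
#' unsupported blocks raise an error naming the block type. Timing
#' metadata are mapped onto an [instrument_config] (window from the TAC
#' range, bins from the ADC resolution); optics fields keep defaults.
#'
#' @param path Path to an `.sdt` file.
#' @return A `decay_stack` (without ground truth).
#' @seealso [write_sdt_fixture()] for generating synthetic files in this
#'   dialect for testing.
#' @export
read_sdt <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hd <- read_sdt_header(con)
  if (hd$no_of_meas_desc_blocks < 1) stop("SDT: no measurement description")
  seek(con, hd$meas_desc_block_offs)
  scan_x <- readBin(con, integer(), 1, 4, endian = "little")
  scan_y <- readBin(con, integer(), 1, 4, endian = "little")
  adc_re <- readBin(con, integer(), 1, 4, endian = "little")
  tac_range <- readBin(con, numeric(), 1, 4, endian = "little")
  tac_gain <- readBin(con, integer(), 1, 4, endian = "little")
  if (adc_re < 2 || scan_x < 1 || scan_y < 1)
    stop("SDT: implausible measurement description (adc_re ", adc_re, ")")
  seek(con, hd$data_block_offs)
  bh <- list(block_no = readBin(con, integer(), 1, 2, endian = "little"),
             data_offs = readBin(con, integer(), 1, 4, endian = "little"),
             next_block_offs = readBin(con, integer(), 1, 4, endian = "little"),
             block_type = readBin(con, integer(), 1, 2, signed = FALSE,
                                  endian = "little"),
             meas_desc_block_no = readBin(con, integer(), 1, 2, endian = "little"),
             lblock_no = readBin(con, integer(), 1, 4, endian = "little"),
             block_length = readBin(con, integer(), 1, 4, endian = "little"))
  if (bh$block_type != 1L)
    stop("SDT: unsupported data block type ", bh$block_type,
         " (only uncompressed uint16 type 1 is readable)")
  n <- scan_x * scan_y * adc_re
  if (bh$block_length != 2L * n)
    stop("SDT: data block length ", bh$block_length,
         " does not match ", scan_x, "x", scan_y, "x", adc_re, " uint16")
  seek(con, bh$data_offs)
  vals <- readBin(con, integer(), n, 2, signed = FALSE, endian = "little")
  # time channel fastest, then x, then y
  counts <- aperm(array(vals, dim = c(adc_re, scan_x, scan_y)), c(2, 3, 1))
  window_ns <- tac_range * 1e9 / max(tac_gain, 1)
  cfg <- instrument_config(n_bins = adc_re, window = window_ns)
  structure(list(counts = counts, config = cfg, truth = NULL),
            class = "decay_stack")
}

#' Write a synthetic SDT fixture file
#'
#' Emits a file in exactly the documented subset dialect that
#' [read_sdt()] consumes (see that help page for the byte layout). This
#' exists to build small synthetic test inputs at run time; it is not a
#' general SDT writer and files from it should be treated as synthetic
#' fixtures only.
#'
#' @param counts Integer X x Y x T array (values < 65536).
#' @param window Timing window (ns) encoded as the TAC range.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sdt_fixture <- function(counts, window, path) {
  d <- dim(counts)
  stopifnot(length(d) == 3, max(counts) < 65536, min(counts) >= 0)
  info <- charToRaw("*IDENTIFICATION\r\nsynthetic fiberhdim fixture\r\n*END\r\n")
  header_len <- 42L
  info_offs <- header_len
  meas_offs <- info_offs + length(info)
  meas_len <- 64L
  dbh_offs <- meas_offs + meas_len
  data_offs <- dbh_offs + 22L
  n <- prod(d)
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(as.integer(x), con, size = size,
                                  endian = "little")
  w(15, 2)                      # revision
  w(info_offs, 4); w(length(info), 2)
  w(0, 4); w(0, 2)              # no setup block
  w(dbh_offs, 4); w(1, 2)       # one data block
  w(2L * n, 4)
  w(meas_offs, 4); w(1, 2); w(meas_len, 2)
  w(0x5555, 2)                  # header_valid magic
  w(0, 4); w(0, 2); w(0, 2)
  writeBin(info, con)
  w(d[1], 4); w(d[2], 4); w(d[3], 4)
  writeBin(window * 1e-9, con, size = 4, endian = "little")  # tac_range (s)
  w(1, 4)                       # tac_gain
  writeBin(raw(meas_len - 20L), con)
  w(1, 2); w(data_offs, 4); w(0, 4)   # block_no, data_offs, next
  w(1, 2)                       # block_type 1 = uncompressed uint16
  w(1, 2); w(1, 4); w(2L * n, 4)
  vals <- as.integer(aperm(counts, c(3, 1, 2)))
  writeBin(vals, con, size = 2, endian = "little")
  invisible(path)
}

#' Write a label mask as single-page integer TIFF
#'
#' @param mask Integer matrix of ROI ids.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(max(mask) <= 65535, min(mask) >= 0)
  tiff::writeTIFF(as.matrix(mask) / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Read a label mask written by [write_mask()]
#'
#' @param path TIFF path.
#' @return Integer matrix of ROI ids.
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Write a run manifest
#'
#' Records the configuration hash, seed, package version and wall time of
#' a pipeline run, so any seeded command is reproducible end to end.
#'
#' @param config An [instrument_config] (or any serializable list).
#' @param seed Seed used.
#' @param path Output JSON path.
#' @param extra Optional named list of additional fields.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(config, seed, path, extra = list()) {
  tmp <- tempfile()
  writeLines(as.character(config_to_json(config)), tmp)
  manifest <- c(list(
    config_md5 = unname(tools::md5sum(tmp)),
    seed = seed,
    package_version = as.character(utils::packageVersion("fiberhdim")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  unlink(tmp)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}
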