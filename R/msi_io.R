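# In-memory data model for MSI datasets and imzML/ibd I/O.
#
# An msi_dataset holds one rectangular acquisition grid. Spectra are kept
# per pixel (processed-mode view); continuous-mode imzML collapses to the
# same representation on read. All internal coordinates are 0-based
# (col, row); imzML's 1-based convention is converted only here.

#' Construct an MSI dataset
#'
#' @param width,height grid dimensions in pixels.
#' @param coords integer matrix (n x 2) of 0-based (col, row) pixel
#'   positions, one row per acquired spectrum.
#' @param spectra list of length n; each element a list with numeric
#'   vectors `mz` (strictly ascending, Da), `intensity` (same length,
#'   non-negative) and optionally `ook0` (inverse reduced mobility,
#'   V s/cm^2, same length).
#' @param polarity `"positive"` or `"negative"`.
#' @param pixel_size pixel edge length in micrometres (default 10, the
#'   raster step used for cell imaging).
#' @param mass_range numeric length-2 (low, high) scan range in Da.
#'   Defaults to 400-1000 for positive mode and 200-1000 for negative
#'   mode, the instrument scan ranges used for single-cell work.
#' @param mobility_range numeric length-2 1/K0 scan range; default
#'   c(0.90, 1.60).
#'
#' @return an object of class `msi_dataset`.
#' @export
msi_dataset <- function(width, height, coords, spectra,
                        polarity = c("positive", "negative"),
                        pixel_size = 10,
                        mass_range = NULL,
                        mobility_range = c(0.90, 1.60)) {
  polarity <- match.arg(polarity)
  if (is.null(mass_range)) {
    mass_range <- if (polarity == "positive") c(400, 1000) else c(200, 1000)
  }
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(width >= 0, height >= 0, length(mass_range) == 2,
            mass_range[1] < mass_range[2])
  coords <- matrix(as.integer(coords), ncol = 2,
                   dimnames = list(NULL, c("col", "row")))
  n <- nrow(coords)
  if (length(spectra) != n)
    stop("'spectra' must have one element per coordinate row")
  if (n > 0) {
    if (any(coords[, 1] < 0L) || any(coords[, 1] >= width) ||
        any(coords[, 2] < 0L) || any(coords[, 2] >= height))
      stop("pixel coordinates outside the ", width, "x", height, " grid")
    if (anyDuplicated(coords[, 1] + as.numeric(coords[, 2]) * width))
      stop("duplicate pixel coordinate")
  }
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    m <- sp$mz
    if (length(m) != length(sp$intensity))
      stop("pixel (", coords[i, 1], ",", coords[i, 2],
           "): mz and intensity lengths differ")
    if (length(m) > 1 && any(diff(m) <= 0))
      stop("pixel (", coords[i, 1], ",", coords[i, 2],
           "): m/z values not strictly ascending")
    if (any(sp$intensity < 0))
      stop("pixel (", coords[i, 1], ",", coords[i, 2],
           "): negative intensity")
    if (!is.null(sp$ook0)) {
      if (length(sp$ook0) != length(m))
        stop("pixel (", coords[i, 1], ",", coords[i, 2],
             "): ook0 length mismatch")
      ok <- is.na(sp$ook0) | (sp$ook0 >= mobility_range[1] &
                                sp$ook0 <= mobility_range[2])
      if (!all(ok))
        stop("pixel (", coords[i, 1], ",", coords[i, 2],
             "): 1/K0 outside mobility scan range")
    }
  }
  structure(list(width = width, height = height,
                 pixel_size = pixel_size, polarity = polarity,
                 mass_range = as.numeric(mass_range),
                 mobility_range = as.numeric(mobility_range),
                 coords = coords, spectra = spectra),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  npk <- sum(vapply(x$spectra, function(s) length(s$mz), integer(1)))
  cat("msi_dataset: ", x$width, " x ", x$height, " px (",
      x$pixel_size, " um raster), ", x$polarity, " mode\n", sep = "")
  cat("  mass range ", x$mass_range[1], "-", x$mass_range[2], " Da; ",
      nrow(x$coords), " pixel spectra, ", npk, " data points",
      if (msi_has_mobility(x)) "; 1/K0 present" else "", "\n", sep = "")
  invisible(x)
}

#' Number of acquired pixels
#' @param dataset an `msi_dataset`.
#' @export
n_pixels <- function(dataset) nrow(dataset$coords)

#' Does any spectrum carry mobility values?
#' @param dataset an `msi_dataset`.
#' @export
msi_has_mobility <- function(dataset) {
  any(vapply(dataset$spectra,
             function(s) !is.null(s$ook0) && any(!is.na(s$ook0)),
             logical(1)))
}

#' Retrieve the spectrum at a pixel
#' @param dataset an `msi_dataset`.
#' @param col,row 0-based pixel coordinates.
#' @return the spectrum list, or NULL when the pixel was not acquired.
#' @export
msi_pixel <- function(dataset, col, row) {
  i <- which(dataset$coords[, 1] == col & dataset$coords[, 2] == row)
  if (length(i) == 0) NULL else dataset$spectra[[i]]
}

# Flatten all spectra into parallel vectors sorted by m/z; used by the
# windowed-sum operations. pixel is the row index into dataset$coords.
msi_flatten <- function(dataset) {
  lens <- vapply(dataset$spectra, function(s) length(s$mz), integer(1))
  mz <- unlist(lapply(dataset$spectra, `[[`, "mz"), use.names = FALSE)
  intensity <- unlist(lapply(dataset$spectra, `[[`, "intensity"),
                      use.names = FALSE)
  ook0 <- unlist(lapply(dataset$spectra, function(s) {
    if (is.null(s$ook0)) rep(NA_real_, length(s$mz)) else s$ook0
  }), use.names = FALSE)
  pixel <- rep.int(seq_along(lens), lens)
  if (is.null(mz)) mz <- numeric(0)
  if (is.null(intensity)) intensity <- numeric(0)
  if (is.null(ook0)) ook0 <- numeric(0)
  o <- order(mz)
  list(mz = mz[o], intensity = intensity[o], ook0 = ook0[o],
       pixel = pixel[o], n_pixels = length(lens))
}

# Indices of sorted vector `mz` falling in the closed interval [lo, hi].
mz_window_idx <- function(mz, lo, hi) {
  a <- findInterval(lo, mz, left.open = TRUE)  # count of mz < lo
  b <- findInterval(hi, mz)                    # count of mz <= hi
  if (b > a) seq.int(a + 1L, b) else integer(0)
}

## ---------------------------------------------------------------- imzML --

.IMZML_HEADER <- paste0(
  '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
  '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
  '  <cvList count="3">\n',
  '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" version="1.3.1" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>\n',
  '    <cv id="UO" fullName="Unit Ontology" version="1.15" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>\n',
  '    <cv id="IMS" fullName="Imaging MS Ontology" version="0.9.1" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>\n',
  '  </cvList>\n')

# byte layout codes for binary arrays
.IMZML_DTYPES <- c("MS:1000523" = "double", "MS:1000521" = "float",
                   "MS:1000522" = "long",   "MS:1000519" = "int")
.IMZML_DSIZES <- c("MS:1000523" = 8L, "MS:1000521" = 4L,
                   "MS:1000522" = 8L, "MS:1000519" = 4L)

#' Write an MSI dataset as imzML
#'
#' Writes processed-mode imzML (per-pixel m/z axes) with 64-bit float
#' arrays and an external `.ibd` binary companion. When mobility values
#' are present they are stored in a plain-text sidecar
#' `<path>.mobility.csv` with columns `col,row,index,ook0` (0-based index
#' into the pixel's peak array); core imzML has no per-peak mobility slot,
#' and the sidecar keeps the main file standard-conformant. Output is
#' deterministic: the file UUID is derived from the binary payload, so
#' identical datasets produce byte-identical files.
#'
#' @param dataset an `msi_dataset`.
#' @param path output path ending in `.imzML`.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(dataset, path) {
  stopifnot(inherits(dataset, "msi_dataset"))
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  n <- n_pixels(dataset)

  # binary payload (without uuid) first, so the uuid can be content-derived
  payload <- raw(0)
  offsets <- matrix(0, n, 2)  # mz offset, intensity offset (after 16B uuid)
  lens <- integer(n)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con), add = TRUE)
  pos <- 16  # uuid occupies the first 16 bytes of the ibd
  for (i in seq_len(n)) {
    sp <- dataset$spectra[[i]]
    lens[i] <- length(sp$mz)
    offsets[i, 1] <- pos
    writeBin(as.double(sp$mz), con, size = 8, endian = "little")
    pos <- pos + 8 * lens[i]
    offsets[i, 2] <- pos
    writeBin(as.double(sp$intensity), con, size = 8, endian = "little")
    pos <- pos + 8 * lens[i]
  }
  payload <- rawConnectionValue(con)

  # content-derived 16-byte uuid (md5 of the payload)
  tf <- tempfile(); on.exit(unlink(tf), add = TRUE)
  writeBin(payload, tf)
  uuid_hex <- unname(tools::md5sum(tf))
  uuid_bytes <- as.raw(strtoi(substring(uuid_hex,
                                        seq(1, 31, 2), seq(2, 32, 2)), 16L))
  writeBin(c(uuid_bytes, payload), ibd_path)
  ibd_md5 <- toupper(unname(tools::md5sum(ibd_path)))
  uuid_fmt <- paste0("{", substr(uuid_hex, 1, 8), "-",
                     substr(uuid_hex, 9, 12), "-", substr(uuid_hex, 13, 16),
                     "-", substr(uuid_hex, 17, 20), "-",
                     substr(uuid_hex, 21, 32), "}")

  pol_acc <- if (dataset$polarity == "positive") "MS:1000130" else "MS:1000129"
  pol_name <- paste(dataset$polarity, "scan")

  out <- file(path, "wb")  # binary mode: byte-identical across platforms
  on.exit(close(out), add = TRUE)
  w <- function(...) writeLines(paste0(...), out, sep = "\n")
  cat(.IMZML_HEADER, file = out)
  w('  <fileDescription>')
  w('    <fileContent>')
  w('      <cvParam cvRef="IMS" accession="IMS:1000031" name="processed" value=""/>')
  w('      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="', uuid_fmt, '"/>')
  w('      <cvParam cvRef="IMS" accession="IMS:1000090" name="ibd MD5" value="', ibd_md5, '"/>')
  w('      <cvParam cvRef="MS" accession="', pol_acc, '" name="', pol_name, '" value=""/>')
  w('    </fileContent>')
  w('  </fileDescription>')
  w('  <referenceableParamGroupList count="2">')
  w('    <referenceableParamGroup id="mzArray">')
  w('      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>')
  w('      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>')
  w('      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>')
  w('      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>')
  w('    </referenceableParamGroup>')
  w('    <referenceableParamGroup id="intensityArray">')
  w('      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>')
  w('      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>')
  w('      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>')
  w('      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>')
  w('    </referenceableParamGroup>')
  w('  </referenceableParamGroupList>')
  w('  <softwareList count="1">')
  w('    <software id="scmsi" version="0.1.0"/>')
  w('  </softwareList>')
  w('  <scanSettingsList count="1">')
  w('    <scanSettings id="scanSettings1">')
  w('      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="', dataset$width, '"/>')
  w('      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="', dataset$height, '"/>')
  w('      <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="', dataset$pixel_size, '"/>')
  w('      <cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="', dataset$pixel_size, '"/>')
  w('    </scanSettings>')
  w('  </scanSettingsList>')
  w('  <instrumentConfigurationList count="1">')
  w('    <instrumentConfiguration id="IC1"/>')
  w('  </instrumentConfigurationList>')
  w('  <dataProcessingList count="1">')
  w('    <dataProcessing id="DP1">')
  w('      <processingMethod order="1" softwareRef="scmsi">')
  w('        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>')
  w('      </processingMethod>')
  w('    </dataProcessing>')
  w('  </dataProcessingList>')
  w('  <run defaultInstrumentConfigurationRef="IC1" id="run1">')
  w('    <spectrumList count="', n, '" defaultDataProcessingRef="DP1">')
  for (i in seq_len(n)) {
    cx <- dataset$coords[i, 1] + 1L  # imzML is 1-based
    cy <- dataset$coords[i, 2] + 1L
    w('      <spectrum defaultArrayLength="0" id="spectrum=', i,
      '" index="', i - 1L, '">')
    w('        <cvParam cvRef="MS" accession="', pol_acc, '" name="',
      pol_name, '" value=""/>')
    w('        <scanList count="1">')
    w('          <scan instrumentConfigurationRef="IC1">')
    w('            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="', cx, '"/>')
    w('            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="', cy, '"/>')
    w('          </scan>')
    w('        </scanList>')
    w('        <binaryDataArrayList count="2">')
    w('          <binaryDataArray encodedLength="0">')
    w('            <referenceableParamGroupRef ref="mzArray"/>')
    w('            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="', lens[i], '"/>')
    w('            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="', 8L * lens[i], '"/>')
    w('            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="', format(offsets[i, 1], scientific = FALSE), '"/>')
    w('            <binary/>')
    w('          </binaryDataArray>')
    w('          <binaryDataArray encodedLength="0">')
    w('            <referenceableParamGroupRef ref="intensityArray"/>')
    w('            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="', lens[i], '"/>')
    w('            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="', 8L * lens[i], '"/>')
    w('            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="', format(offsets[i, 2], scientific = FALSE), '"/>')
    w('            <binary/>')
    w('          </binaryDataArray>')
    w('        </binaryDataArrayList>')
    w('      </spectrum>')
  }
  w('    </spectrumList>')
  w('  </run>')
  w('</mzML>')

  # mobility sidecar
  side <- paste0(path, ".mobility.csv")
  if (msi_has_mobility(dataset)) {
    rows <- lapply(seq_len(n), function(i) {
      k0 <- dataset$spectra[[i]]$ook0
      if (is.null(k0)) return(NULL)
      j <- which(!is.na(k0))
      if (length(j) == 0) return(NULL)
      data.frame(col = unname(dataset$coords[i, 1]),
                 row = unname(dataset$coords[i, 2]),
                 index = unname(j - 1L), ook0 = unname(k0[j]),
                 row.names = NULL)
    })
    tab <- do.call(rbind, rows)
    write.csv(tab, side, row.names = FALSE, quote = FALSE)
  } else if (file.exists(side)) {
    unlink(side)
  }
  invisible(path)
}

#' Read an imzML dataset
#'
#' Supports both processed (per-pixel m/z axis) and continuous (shared
#' axis) binary modes and 32-/64-bit float arrays. 1-based imzML pixel
#' coordinates are converted to the package's 0-based (col, row)
#' convention. A `<path>.mobility.csv` sidecar written by
#' [write_imzml()] is restored automatically when present.
#'
#' @param path path to the `.imzML` file; the `.ibd` companion must sit
#'   next to it.
#' @param polarity fallback polarity when the file metadata carries none.
#' @param pixel_size,mass_range,mobility_range overrides for metadata the
#'   format does not carry; `NULL` means use the file value or default.
#' @return an `msi_dataset`.
#' @export
read_imzml <- function(path, polarity = NULL, pixel_size = NULL,
                       mass_range = NULL, mobility_range = c(0.90, 1.60)) {
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(path)) stop("imzML file not found: ", path)
  if (!file.exists(ibd_path))
    stop("binary companion not found; expected ", ibd_path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "m")

  cv_value <- function(node, accession, xp = ".//m:cvParam") {
    hits <- xml2::xml_find_all(
      node, paste0(xp, "[@accession='", accession, "']"), ns)
    if (length(hits) == 0) NULL else xml2::xml_attr(hits[[1]], "value")
  }
  has_cv <- function(node, accession) {
    length(xml2::xml_find_all(
      node, paste0(".//m:cvParam[@accession='", accession, "']"), ns)) > 0
  }

  fc <- xml2::xml_find_first(doc, ".//m:fileDescription/m:fileContent", ns)
  continuous <- has_cv(fc, "IMS:1000030")
  file_pol <- if (has_cv(fc, "MS:1000130")) "positive"
              else if (has_cv(fc, "MS:1000129")) "negative" else NULL

  # datatype per referenceable param group
  rpgs <- xml2::xml_find_all(doc, ".//m:referenceableParamGroup", ns)
  group_dtype <- list(); group_kind <- list()
  for (g in rpgs) {
    id <- xml2::xml_attr(g, "id")
    accs <- xml2::xml_attr(xml2::xml_find_all(g, ".//m:cvParam", ns),
                           "accession")
    dt <- intersect(names(.IMZML_DTYPES), accs)
    if (length(dt)) group_dtype[[id]] <- dt[1]
    if ("MS:1000514" %in% accs) group_kind[[id]] <- "mz"
    if ("MS:1000515" %in% accs) group_kind[[id]] <- "intensity"
  }

  ss <- xml2::xml_find_first(doc, ".//m:scanSettings", ns)
  wx <- cv_value(ss, "IMS:1000042"); hy <- cv_value(ss, "IMS:1000043")
  psx <- cv_value(ss, "IMS:1000046")

  ibd <- file(ibd_path, "rb")
  on.exit(close(ibd), add = TRUE)

  read_array <- function(offset, length, dtype) {
    seek(ibd, where = offset, origin = "start")
    what <- .IMZML_DTYPES[[dtype]]
    sz <- .IMZML_DSIZES[[dtype]]
    v <- readBin(ibd, what = if (what %in% c("double", "float")) "double"
                 else "integer",
                 n = length, size = sz, endian = "little")
    as.numeric(v)
  }

  spectra_nodes <- xml2::xml_find_all(doc, ".//m:spectrum", ns)
  n <- length(spectra_nodes)
  coords <- matrix(0L, n, 2)
  spectra <- vector("list", n)
  spec_pol <- NULL
  for (i in seq_len(n)) {
    sn <- spectra_nodes[[i]]
    x <- as.integer(cv_value(sn, "IMS:1000050"))
    y <- as.integer(cv_value(sn, "IMS:1000051"))
    if (is.na(x) || is.na(y))
      stop("spectrum ", i, " lacks pixel position metadata")
    coords[i, ] <- c(x - 1L, y - 1L)
    if (is.null(spec_pol)) {
      if (has_cv(sn, "MS:1000130")) spec_pol <- "positive"
      else if (has_cv(sn, "MS:1000129")) spec_pol <- "negative"
    }
    arrays <- list()
    for (bda in xml2::xml_find_all(sn, ".//m:binaryDataArray", ns)) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(bda, ".//m:referenceableParamGroupRef", ns),
        "ref")
      kind <- group_kind[[ref]]
      if (is.null(kind)) next
      len <- as.integer(cv_value(bda, "IMS:1000103"))
      off <- as.numeric(cv_value(bda, "IMS:1000102"))
      dt <- group_dtype[[ref]]
      if (is.null(dt)) dt <- "MS:1000523"
      arrays[[kind]] <- read_array(off, len, dt)
    }
    if (is.null(arrays$mz) || is.null(arrays$intensity))
      stop("spectrum ", i, " lacks m/z or intensity arrays")
    if (length(arrays$mz) > 1 && any(diff(arrays$mz) <= 0))
      stop("non-ascending m/z in spectrum at pixel (",
           coords[i, 1], ",", coords[i, 2], ")")
    spectra[[i]] <- list(mz = arrays$mz, intensity = arrays$intensity,
                         ook0 = NULL)
  }

  pol <- file_pol
  if (is.null(pol)) pol <- spec_pol
  if (is.null(pol)) pol <- polarity
  if (is.null(pol))
    stop("file carries no polarity metadata; pass polarity = ",
         "\"positive\" or \"negative\"")

  if (is.null(pixel_size))
    pixel_size <- if (!is.null(psx)) as.numeric(psx) else 10
  width <- if (!is.null(wx)) as.integer(wx) else max(coords[, 1] + 1L, 0L)
  height <- if (!is.null(hy)) as.integer(hy) else max(coords[, 2] + 1L, 0L)
  if (n > 0) {
    width <- max(width, max(coords[, 1]) + 1L)
    height <- max(height, max(coords[, 2]) + 1L)
  }

  # mobility sidecar
  side <- paste0(path, ".mobility.csv")
  if (file.exists(side)) {
    tab <- read.csv(side)
    key <- paste(coords[, 1], coords[, 2])
    by_pix <- split(tab, paste(tab$col, tab$row))
    for (k in names(by_pix)) {
      i <- match(k, key)
      if (is.na(i)) next
      sp <- spectra[[i]]
      k0 <- rep(NA_real_, length(sp$mz))
      k0[by_pix[[k]]$index + 1L] <- by_pix[[k]]$ook0
      spectra[[i]]$ook0 <- k0
    }
  }

  msi_dataset(width = width, height = height, coords = coords,
              spectra = spectra, polarity = pol, pixel_size = pixel_size,
              mass_range = if (is.null(mass_range)) NULL else mass_range,
              mobility_range = mobility_range)
}

## --------------------------------------------------------- registration --

#' Fit a registration transform from control points
#'
#' Least-squares similarity (scale + rotation + translation) transform
#' mapping `src_points` onto `dst_points`, the closed-form Procrustes
#' solution. Registration between serial acquisition runs of the same
#' slide uses few hand-placed control points (pen marks), for which the
#' rigid-slide similarity model is appropriate; a full affine fit is
#' available via `kind = "affine"`.
#'
#' @param src_points,dst_points numeric matrices (n x 2) of matching
#'   (x, y) control points, n >= 2 (3 for affine), not all coincident.
#' @param kind `"similarity"` (default) or `"affine"`.
#' @return a `registration_transform` with elements `A` (2 x 2 linear
#'   part), `t` (translation), `scale`, `rotation` (radians, similarity
#'   only) and `rmse` (residual, pixel units).
#' @export
fit_registration <- function(src_points, dst_points,
                             kind = c("similarity", "affine")) {
  kind <- match.arg(kind)
  src <- matrix(as.numeric(src_points), ncol = 2)
  dst <- matrix(as.numeric(dst_points), ncol = 2)
  if (nrow(src) != nrow(dst)) stop("control point sets differ in length")
  min_n <- if (kind == "similarity") 2L else 3L
  if (nrow(src) < min_n)
    stop("need at least ", min_n, " control point pairs, got ", nrow(src))
  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  Xc <- sweep(src, 2, mu_s); Yc <- sweep(dst, 2, mu_d)
  var_s <- sum(Xc^2) / nrow(src)
  if (var_s < .Machine$double.eps)
    stop("degenerate control points: all source points coincide")
  if (kind == "similarity") {
    Sigma <- crossprod(Yc, Xc) / nrow(src)
    sv <- svd(Sigma)
    S <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
    R <- sv$u %*% S %*% t(sv$v)
    scale <- sum(diag(diag(sv$d) %*% S)) / var_s
    if (scale <= 0) stop("degenerate control points: non-positive scale")
    A <- scale * R
    tvec <- mu_d - A %*% mu_s
    rotation <- atan2(R[2, 1], R[1, 1])
  } else {
    fx <- stats::lm.fit(cbind(1, src), dst[, 1])
    fy <- stats::lm.fit(cbind(1, src), dst[, 2])
    A <- rbind(fx$coefficients[2:3], fy$coefficients[2:3])
    tvec <- c(fx$coefficients[1], fy$coefficients[1])
    scale <- sqrt(abs(det(A)))
    rotation <- NA_real_
  }
  tf <- structure(list(kind = kind, A = unname(A),
                       t = as.numeric(tvec), scale = as.numeric(scale),
                       rotation = as.numeric(rotation), rmse = NA_real_),
                  class = "registration_transform")
  pred <- apply_transform(tf, src)
  tf$rmse <- sqrt(mean(rowSums((pred - dst)^2)))
  tf
}

#' Apply a registration transform to points
#' @param transform a `registration_transform`.
#' @param points numeric matrix (n x 2) or length-2 vector.
#' @return transformed points, same shape.
#' @export
apply_transform <- function(transform, points) {
  p <- matrix(as.numeric(points), ncol = 2)
  out <- p %*% t(transform$A)
  out[, 1] <- out[, 1] + transform$t[1]
  out[, 2] <- out[, 2] + transform$t[2]
  if (is.vector(points) && length(points) == 2) as.numeric(out) else out
}

#' Invert a registration transform
#' @param transform a `registration_transform`.
#' @return the inverse `registration_transform`.
#' @export
invert_transform <- function(transform) {
  Ai <- solve(transform$A)
  structure(list(kind = transform$kind, A = Ai,
                 t = as.numeric(-Ai %*% transform$t),
                 scale = 1 / transform$scale,
                 rotation = if (is.na(transform$rotation)) NA_real_
                            else -transform$rotation,
                 rmse = transform$rmse),
            class = "registration_transform")
}

#' Identity transform
#' @return a `registration_transform` that maps every point to itself.
#' @export
identity_transform <- function() {
  structure(list(kind = "similarity", A = diag(2), t = c(0, 0),
                 scale = 1, rotation = 0, rmse = 0),
            class = "registration_transform")
}

#' Build a similarity transform from parameters
#' @param scale scale factor (> 0).
#' @param rotation rotation angle, radians.
#' @param tx,ty translation, pixels.
#' @export
similarity_transform <- function(scale = 1, rotation = 0, tx = 0, ty = 0) {
  stopifnot(scale > 0)
  R <- matrix(c(cos(rotation), sin(rotation),
                -sin(rotation), cos(rotation)), 2, 2)
  structure(list(kind = "similarity", A = scale * R, t = c(tx, ty),
                 scale = scale, rotation = rotation, rmse = NA_real_),
            class = "registration_transform")
}

#' @export
print.registration_transform <- function(x, ...) {
  cat("registration_transform (", x$kind, ")\n", sep = "")
  if (x$kind == "similarity")
    cat(sprintf("  scale %.6g, rotation %.6g rad, translation (%.4g, %.4g)\n",
                x$scale, x$rotation, x$t[1], x$t[2]))
  else
    cat("  A = [", paste(signif(t(x$A), 6), collapse = " "),
        "], t = (", paste(signif(x$t, 6), collapse = ", "), ")\n")
  if (!is.na(x$rmse)) cat(sprintf("  control-point rmse %.4g px\n", x$rmse))
  invisible(x)
}

#' Read registration control points from CSV
#'
#' Expects columns `src_x, src_y, dst_x, dst_y`, one control point pair
#' per row.
#' @param path CSV path.
#' @return list with matrices `src` and `dst`.
#' @export
read_control_points <- function(path) {
  tab <- read.csv(path)
  need <- c("src_x", "src_y", "dst_x", "dst_y")
  if (!all(need %in% names(tab)))
    stop("control point file must have columns ",
         paste(need, collapse = ", "))
  list(src = as.matrix(tab[, c("src_x", "src_y")]),
       dst = as.matrix(tab[, c("dst_x", "dst_y")]))
}
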