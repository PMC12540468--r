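# Minimal imzML input/output.
#
# imzML stores spectral metadata in an mzML-style XML file and the numeric
# arrays in a companion binary ".ibd" file (16-byte UUID header, then raw
# little-endian arrays addressed by byte offset). Two layouts exist:
# "continuous" (one shared m/z axis, written once) and "processed" (each
# spectrum carries its own m/z array). Only uncompressed 32/64-bit float
# and integer arrays are supported here, which covers standard exports.

.IMS_CONTINUOUS <- "IMS:1000030"
.IMS_PROCESSED  <- "IMS:1000031"
.IMS_POS_X      <- "IMS:1000050"
.IMS_POS_Y      <- "IMS:1000051"
.IMS_ARR_LEN    <- "IMS:1000103"
.IMS_ARR_OFF    <- "IMS:1000102"

.imzml_dtype <- function(node) {
  acc <- xml2::xml_attr(xml2::xml_find_all(node, ".//cvParam"), "accession")
  if ("MS:1000523" %in% acc) return(list(what = "double", size = 8L))
  if ("MS:1000521" %in% acc) return(list(what = "double", size = 4L))
  if ("MS:1000522" %in% acc) return(list(what = "integer", size = 8L))
  if ("MS:1000519" %in% acc) return(list(what = "integer", size = 4L))
  stop("unsupported binary data type in imzML (need 32/64-bit float or int)")
}

.cv_value <- function(node, accession) {
  p <- xml2::xml_find_first(
    node, sprintf(".//cvParam[@accession='%s']", accession))
  if (inherits(p, "xml_missing")) return(NA_character_)
  xml2::xml_attr(p, "value")
}

#' Read MSI ion images from an imzML file
#'
#' Supports both continuous and processed binary layouts, uncompressed.
#' The companion `.ibd` file is located by replacing the extension. In
#' processed mode, per-spectrum m/z axes are merged onto a common axis by
#' clustering values closer than `mz_tol` Da; absent m/z values in a pixel
#' are recorded as zero intensity.
#'
#' @param path path to the `.imzML` XML file.
#' @param metaresolution micrometres per pixel step (default 100).
#' @param mz_range instrument mass range (Da).
#' @param mz_tol m/z merge tolerance for processed mode (Da).
#' @return an [msi_raster]. Pixel indices are the imzML x/y positions as
#'   stored (imzML convention is 1-based); the constant offset is
#'   immaterial to registration.
#' @export
read_imzml <- function(path, metaresolution = 100, mz_range = c(70, 1200),
                       mz_tol = 1e-4) {
  ibd <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd, path)) ibd <- paste0(path, ".ibd")
  if (!file.exists(ibd)) stop("companion .ibd file not found: ", ibd)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  fc <- xml2::xml_find_first(doc, ".//fileDescription/fileContent")
  acc <- xml2::xml_attr(xml2::xml_find_all(fc, ".//cvParam"), "accession")
  continuous <- .IMS_CONTINUOUS %in% acc
  if (!continuous && !(.IMS_PROCESSED %in% acc)) {
    stop("imzML fileContent declares neither continuous nor processed mode")
  }

  # data types may be declared on referenceable param groups
  grp_dtype <- list()
  for (g in xml2::xml_find_all(doc, ".//referenceableParamGroup")) {
    id <- xml2::xml_attr(g, "id")
    grp_dtype[[id]] <- tryCatch(.imzml_dtype(g), error = function(e) NULL)
  }

  spectra <- xml2::xml_find_all(doc, ".//run//spectrum")
  if (length(spectra) == 0L) stop("no spectra in imzML file")
  con <- file(ibd, "rb")
  on.exit(close(con))

  read_array <- function(bda) {
    ref <- xml2::xml_attr(
      xml2::xml_find_first(bda, ".//referenceableParamGroupRef"), "ref")
    dt <- if (!is.na(ref) && !is.null(grp_dtype[[ref]])) grp_dtype[[ref]]
          else .imzml_dtype(bda)
    len <- as.integer(.cv_value(bda, .IMS_ARR_LEN))
    off <- as.numeric(.cv_value(bda, .IMS_ARR_OFF))
    seek(con, where = off, origin = "start")
    readBin(con, what = dt$what, n = len, size = dt$size, endian = "little")
  }

  is_mz_array <- function(bda) {
    ref <- xml2::xml_attr(
      xml2::xml_find_first(bda, ".//referenceableParamGroupRef"), "ref")
    accs <- xml2::xml_attr(xml2::xml_find_all(bda, ".//cvParam"), "accession")
    if ("MS:1000514" %in% accs) return(TRUE)
    if ("MS:1000515" %in% accs) return(FALSE)
    if (!is.na(ref)) {
      g <- xml2::xml_find_first(
        doc, sprintf(".//referenceableParamGroup[@id='%s']", ref))
      gacc <- xml2::xml_attr(xml2::xml_find_all(g, ".//cvParam"), "accession")
      return("MS:1000514" %in% gacc)
    }
    stop("binaryDataArray without m/z or intensity designation")
  }

  n <- length(spectra)
  pos_x <- integer(n); pos_y <- integer(n)
  mz_list <- vector("list", n); int_list <- vector("list", n)
  for (k in seq_len(n)) {
    sp <- spectra[[k]]
    scan <- xml2::xml_find_first(sp, ".//scanList/scan")
    pos_x[k] <- as.integer(.cv_value(scan, .IMS_POS_X))
    pos_y[k] <- as.integer(.cv_value(scan, .IMS_POS_Y))
    for (bda in xml2::xml_find_all(sp, ".//binaryDataArray")) {
      if (is_mz_array(bda)) mz_list[[k]] <- read_array(bda)
      else int_list[[k]] <- read_array(bda)
    }
  }

  if (continuous) {
    mz <- mz_list[[1]]
    mat <- do.call(rbind, int_list)
  } else {
    all_mz <- sort(unique(unlist(mz_list)))
    # cluster m/z values closer than mz_tol onto one axis
    grp <- cumsum(c(TRUE, diff(all_mz) > mz_tol))
    mz <- as.numeric(tapply(all_mz, grp, mean))
    mat <- matrix(0, nrow = n, ncol = length(mz))
    for (k in seq_len(n)) {
      j <- grp[match(mz_list[[k]], all_mz)]
      mat[k, j] <- int_list[[k]]
    }
  }
  msi_raster(meta_x = pos_x, meta_y = pos_y, mz_values = mz, intensity = mat,
             metaresolution = metaresolution, mz_range = mz_range)
}

#' Write an MSI raster to imzML (continuous mode)
#'
#' Emits a minimal continuous-layout imzML/ibd pair: one shared 64-bit m/z
#' axis followed by per-pixel 64-bit intensity arrays, uncompressed.
#' Intended for interchange and round-trip testing of [read_imzml()].
#'
#' @param raster an [msi_raster].
#' @param path output path ending in `.imzML`; the `.ibd` companion is
#'   written alongside.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(raster, path) {
  stopifnot(inherits(raster, "msi_raster"))
  ibd <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd, path)) ibd <- paste0(path, ".ibd")

  mz <- raster$mz_values
  nmz <- length(mz)
  npx <- nrow(raster$pixels)
  con <- file(ibd, "wb")
  uuid_bytes <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  writeBin(uuid_bytes, con)
  writeBin(as.numeric(mz), con, size = 8, endian = "little")
  for (k in seq_len(npx)) {
    writeBin(as.numeric(raster$intensity[k, ]), con, size = 8,
             endian = "little")
  }
  close(con)

  mz_off <- 16
  int_off0 <- 16 + 8 * nmz
  spec <- character(npx)
  for (k in seq_len(npx)) {
    off <- int_off0 + 8 * nmz * (k - 1)
    spec[k] <- sprintf(
'   <spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">
    <scanList count="1">
     <scan>
      <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>
     </scan>
    </scanList>
    <binaryDataArrayList count="2">
     <binaryDataArray encodedLength="0">
      <referenceableParamGroupRef ref="mzArray"/>
      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>
      <binary/>
     </binaryDataArray>
     <binaryDataArray encodedLength="0">
      <referenceableParamGroupRef ref="intensityArray"/>
      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>
      <binary/>
     </binaryDataArray>
    </binaryDataArrayList>
   </spectrum>',
      k - 1L, k, nmz,
      raster$pixels$meta_x[k], raster$pixels$meta_y[k],
      nmz, mz_off, nmz, off)
  }

  xml <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">
 <fileDescription>
  <fileContent>
   <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>
  </fileContent>
 </fileDescription>
 <referenceableParamGroupList count="2">
  <referenceableParamGroup id="mzArray">
   <cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>
   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>
   <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>
  </referenceableParamGroup>
  <referenceableParamGroup id="intensityArray">
   <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>
   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>
   <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>
  </referenceableParamGroup>
 </referenceableParamGroupList>
 <run id="run0">
  <spectrumList count="%d">
%s
  </spectrumList>
 </run>
</mzML>', npx, paste(spec, collapse = "\n"))
  writeLines(xml, path)
  invisible(path)
}
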