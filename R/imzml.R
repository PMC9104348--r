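# Minimal imzML 1.1 writer/reader for centroid MSI data.
# Processed mode (per-pixel m/z arrays) is written; both processed and
# continuous mode are read. Binary arrays live in the companion .ibd file,
# referenced by external offset/length; the XML carries the imaging MS
# (IMS) and PSI-MS controlled-vocabulary parameters required by common
# readers. Only 32/64-bit float encodings are supported, uncompressed.

imzml_cv_header <- function() {
  paste0(
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    '</cvList>'
  )
}

random_uuid <- function() {
  b <- as.integer(floor(stats::runif(16, 0, 256)))
  b[7] <- bitwOr(bitwAnd(b[7], 0x0F), 0x40)  # version 4
  b[9] <- bitwOr(bitwAnd(b[9], 0x3F), 0x80)
  h <- sprintf("%02x", b)
  paste0(paste(h[1:4], collapse = ""), "-", paste(h[5:6], collapse = ""), "-",
         paste(h[7:8], collapse = ""), "-", paste(h[9:10], collapse = ""), "-",
         paste(h[11:16], collapse = ""))
}

#' Write an MSI dataset as an imzML/ibd pair
#'
#' Writes processed-mode imzML 1.1 (one m/z and one intensity array per
#' pixel) with 64-bit m/z and 32-bit intensity encodings.
#'
#' @param dataset an [msi_dataset()].
#' @param path output path of the `.imzML` file; the `.ibd` file is written
#'   next to it with the same stem.
#' @return Invisibly, the imzML path.
#' @export
write_imzml <- function(dataset, path) {
  stopifnot(inherits(dataset, "msi_dataset"))
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  uuid <- random_uuid()
  uuid_bytes <- as.raw(strtoi(substring(gsub("-", "", uuid),
                                        seq(1, 31, 2), seq(2, 32, 2)), 16L))
  con <- file(ibd_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid_bytes, con)
  offset <- 16
  n <- nrow(dataset$coords)
  mz_off <- mz_len <- int_off <- int_len <- integer(n)
  for (i in seq_len(n)) {
    mz <- dataset$mz[[i]]
    writeBin(as.numeric(mz), con, size = 8, endian = "little")
    mz_off[i] <- offset
    mz_len[i] <- length(mz)
    offset <- offset + 8 * length(mz)
    int <- dataset$intensity[[i]]
    writeBin(as.numeric(int), con, size = 4, endian = "little")
    int_off[i] <- offset
    int_len[i] <- length(int)
    offset <- offset + 4 * length(int)
  }

  xmax <- max(dataset$coords$x)
  ymax <- max(dataset$coords$y)
  pol_cv <- if (dataset$polarity == "-") {
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan"/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan"/>'
  }
  spectra <- character(n)
  for (i in seq_len(n)) {
    spectra[i] <- sprintf(paste0(
      '<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>',
      pol_cv,
      '<scanList count="1">',
      '<scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>',
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>',
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, i, mz_len[i],
      dataset$coords$x[i], dataset$coords$y[i],
      mz_len[i], mz_off[i], 8L * mz_len[i],
      int_len[i], int_off[i], 4L * int_len[i])
  }

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    imzml_cv_header(),
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>',
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>', uuid),
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>',
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '<cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>', xmax),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>', ymax),
    '</scanSettings></scanSettingsList>',
    '<softwareList count="1"><software id="metatrack" version="0.1.0"/></softwareList>',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"/>',
    '</instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="export">',
    '<processingMethod order="1" softwareRef="metatrack">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>',
    '</processingMethod></dataProcessing></dataProcessingList>',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
    sprintf('<spectrumList count="%d">', n),
    paste(spectra, collapse = ""),
    '</spectrumList></run></mzML>'
  )
  writeLines(xml, path)
  invisible(path)
}

#' Load an imzML/ibd pair
#'
#' Reads imzML 1.1 in processed or continuous binary mode (uncompressed
#' 32/64-bit floats). Polarity is taken from the spectrum-level scan CV
#' params when present.
#'
#' @param path path to the `.imzML` file; the `.ibd` file must sit next to
#'   it with the same stem.
#' @return An [msi_dataset()].
#' @export
load_imzml <- function(path) {
  if (!file.exists(path)) stop("imzML file not found: ", path)
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd_path)) stop("binary file not found: ", ibd_path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed imzML XML: ", conditionMessage(e))
  })
  ns <- c(d = xml2::xml_ns(doc)[[1]])

  # binary encoding per referenceable param group
  groups <- xml2::xml_find_all(doc, ".//d:referenceableParamGroup", ns)
  enc <- list()
  for (g in groups) {
    id <- xml2::xml_attr(g, "id")
    acc <- xml2::xml_attr(xml2::xml_find_all(g, "./d:cvParam", ns), "accession")
    size <- if ("MS:1000523" %in% acc) 8L else if ("MS:1000521" %in% acc) 4L else NA_integer_
    kind <- if ("MS:1000514" %in% acc) "mz" else if ("MS:1000515" %in% acc) "intensity" else NA
    enc[[id]] <- list(size = size, kind = kind)
  }

  spectra <- xml2::xml_find_all(doc, ".//d:spectrum", ns)
  if (length(spectra) == 0) stop("imzML contains no spectra")
  con <- file(ibd_path, "rb")
  on.exit(close(con), add = TRUE)

  n <- length(spectra)
  xs <- ys <- integer(n)
  mzl <- intl <- vector("list", n)
  polarity <- "-"
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    accs <- xml2::xml_attr(xml2::xml_find_all(sp, "./d:cvParam", ns), "accession")
    if ("MS:1000130" %in% accs) polarity <- "+"
    pos <- xml2::xml_find_all(sp, ".//d:scan/d:cvParam", ns)
    pacc <- xml2::xml_attr(pos, "accession")
    pval <- xml2::xml_attr(pos, "value")
    xs[i] <- as.integer(pval[pacc == "IMS:1000050"][1])
    ys[i] <- as.integer(pval[pacc == "IMS:1000051"][1])
    for (bda in xml2::xml_find_all(sp, ".//d:binaryDataArray", ns)) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(bda, "./d:referenceableParamGroupRef", ns), "ref")
      meta <- enc[[ref]]
      cvs <- xml2::xml_find_all(bda, "./d:cvParam", ns)
      cacc <- xml2::xml_attr(cvs, "accession")
      cval <- xml2::xml_attr(cvs, "value")
      len <- as.numeric(cval[cacc == "IMS:1000103"][1])
      off <- as.numeric(cval[cacc == "IMS:1000102"][1])
      if (is.na(len) || is.na(off) || is.null(meta) || is.na(meta$size)) {
        stop("unsupported or incomplete binary array metadata in spectrum ", i)
      }
      seek(con, where = off, origin = "start")
      vals <- readBin(con, "double", n = len, size = meta$size,
                      endian = "little")
      if (meta$kind == "mz") mzl[[i]] <- vals else intl[[i]] <- vals
    }
  }
  msi_dataset(data.frame(x = xs, y = ys), mzl, intl,
              mz_range = range(unlist(mzl)), polarity = polarity)
}
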