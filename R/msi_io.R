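# In-memory data model + continuous-mode imzML 1.1 input/output.
#
# The unit every stage transforms is the `ion_image_dataset`: one sample's
# spot grid, a single shared m/z axis (continuous-mode contract), and a
# spots x channels intensity matrix, plus study metadata (group, time point,
# ionization mode).

#' Construct an ion image dataset
#'
#' Bundles one MSI sample: grid coordinates, the shared m/z axis, the
#' spots-by-channels intensity matrix, and study metadata. All downstream
#' stages (preprocessing, peak detection, segmentation, ROC analysis) operate
#' on this container.
#'
#' @param sample_id Character scalar identifying the sample/section.
#' @param group Diet group, `"CTRL"` or `"HFHS"`.
#' @param timepoint Feeding time point, one of `"3d"`, `"1w"`, `"4w"`,
#'   `"8w"`, `"12w"`, `"16w"`.
#' @param mode Ionization mode, `"positive"` or `"negative"`.
#' @param coords Data frame with integer columns `x`, `y` (0-based grid
#'   positions), one row per spot, no duplicates.
#' @param mz Strictly increasing numeric m/z axis (Thomson), shared by all
#'   spots.
#' @param intensities Numeric matrix, `nrow(coords)` rows by `length(mz)`
#'   columns, nonnegative.
#'
#' @return An object of class `ion_image_dataset`.
#' @export
ion_image_dataset <- function(sample_id, group, timepoint, mode,
                              coords, mz, intensities) {
  group     <- match.arg(group, GROUP_LEVELS)
  timepoint <- match.arg(timepoint, TIMEPOINT_LEVELS)
  mode      <- match.arg(mode, MODE_LEVELS)
  coords <- as.data.frame(coords)[, c("x", "y")]
  coords$x <- as.integer(coords$x); coords$y <- as.integer(coords$y)
  intensities <- as.matrix(intensities)
  mz <- as.numeric(mz)
  obj <- structure(
    list(sample_id = as.character(sample_id), group = group,
         timepoint = timepoint, mode = mode,
         coords = coords, mz = mz, intensities = intensities),
    class = "ion_image_dataset")
  validate_dataset(obj)
  obj
}

#' Validate an ion image dataset
#'
#' Checks the container invariants: strictly increasing shared m/z axis,
#' nonnegative intensities, matching dimensions, and no duplicate spot
#' coordinates.
#'
#' @param x An `ion_image_dataset`.
#' @return `x`, invisibly; errors if an invariant is violated.
#' @export
validate_dataset <- function(x) {
  if (!inherits(x, "ion_image_dataset"))
    stop_ovimsi("not an ion_image_dataset")
  if (length(x$mz) < 1L || any(diff(x$mz) <= 0))
    stop_ovimsi("mz axis must be nonempty and strictly increasing")
  if (nrow(x$intensities) != nrow(x$coords))
    stop_ovimsi("intensity rows (", nrow(x$intensities),
                ") != number of spots (", nrow(x$coords), ")")
  if (ncol(x$intensities) != length(x$mz))
    stop_ovimsi("intensity columns != length of mz axis")
  if (anyDuplicated(paste(x$coords$x, x$coords$y, sep = ",")))
    stop_ovimsi("duplicate spot coordinates")
  if (any(x$intensities < 0))
    stop_ovimsi("negative intensities")
  invisible(x)
}

#' @export
print.ion_image_dataset <- function(x, ...) {
  cat(sprintf(
    "ion_image_dataset '%s' [%s, %s, %s mode]\n  %d spots, %d channels, m/z %.2f-%.2f\n",
    x$sample_id, x$group, x$timepoint, x$mode,
    nrow(x$coords), length(x$mz), min(x$mz), max(x$mz)))
  invisible(x)
}

#' Number of spots in a dataset
#' @param x An `ion_image_dataset`.
#' @return Integer spot count.
#' @export
n_spots <- function(x) nrow(x$coords)

# ---------------------------------------------------------------------------
# imzML 1.1, continuous mode.
#
# Layout of the .ibd binary companion: 16-byte UUID, then the shared m/z
# axis as float64, then one float32 intensity block per spectrum. The XML
# carries per-spectrum external offsets/lengths, the standard continuous-mode
# arrangement. Processed-mode files (per-spot axes) are rejected: the whole
# pipeline assumes a common aligned axis.
# ---------------------------------------------------------------------------

ACC_CONTINUOUS <- "IMS:1000030"
ACC_PROCESSED  <- "IMS:1000031"

imzml_paths <- function(path) {
  base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  list(imzml = paste0(base, ".imzML"),
       ibd = paste0(base, ".ibd"),
       sidecar = paste0(base, ".json"))
}

#' Write a dataset as continuous-mode imzML
#'
#' Produces the standard file pair (`.imzML` XML + `.ibd` binary; m/z axis
#' float64, intensities float32) plus a JSON metadata sidecar
#' (`{sample_id, group, timepoint, mode}`) next to them, since imzML has no
#' standard slot for study factors.
#'
#' @param dataset An `ion_image_dataset`.
#' @param path Output path ending in `.imzML` (the `.ibd` and `.json` names
#'   are derived from it).
#' @return The imzML path, invisibly.
#' @export
write_imzml <- function(dataset, path) {
  validate_dataset(dataset)
  if (n_spots(dataset) == 0L)
    stop_ovimsi("refusing to write a dataset with zero spots")
  p <- imzml_paths(path)
  nc <- length(dataset$mz)
  ns <- n_spots(dataset)

  # binary payload (without UUID) first, so the UUID can be its md5 digest --
  # this keeps writes bit-reproducible for identical data
  payload <- tempfile()
  con <- file(payload, "wb")
  writeBin(as.numeric(dataset$mz), con, size = 8, endian = "little")
  for (i in seq_len(ns))
    writeBin(as.numeric(dataset$intensities[i, ]), con, size = 4,
             endian = "little")
  close(con)
  uuid_bytes <- as.raw(strtoi(substring(tools::md5sum(payload)[[1]],
                                        seq(1, 31, 2), seq(2, 32, 2)),
                              base = 16L))
  con <- file(p$ibd, "wb")
  writeBin(uuid_bytes, con)
  writeBin(readBin(payload, "raw", n = file.info(payload)$size), con)
  close(con)
  unlink(payload)

  uuid_str <- paste0("{", format_uuid(uuid_bytes), "}")
  mz_offset <- 16
  mz_enc <- nc * 8
  int_offsets <- mz_offset + mz_enc + (seq_len(ns) - 1L) * nc * 4

  spectra <- vapply(seq_len(ns), function(i) {
    paste0(
      '      <spectrum id="spectrum=', i, '" index="', i - 1L,
      '" defaultArrayLength="', nc, '">\n',
      '        <scanList count="1">\n',
      '          <scan>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="',
      dataset$coords$x[i] + 1L, '"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="',
      dataset$coords$y[i] + 1L, '"/>\n',
      '          </scan>\n',
      '        </scanList>\n',
      '        <binaryDataArrayList count="2">\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <referenceableParamGroupRef ref="mzArray"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="', mz_offset, '"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="', nc, '"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="', mz_enc, '"/>\n',
      '            <binary/>\n',
      '          </binaryDataArray>\n',
      '          <binaryDataArray encodedLength="0">\n',
      '            <referenceableParamGroupRef ref="intensityArray"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="', int_offsets[i], '"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="', nc, '"/>\n',
      '            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="', nc * 4, '"/>\n',
      '            <binary/>\n',
      '          </binaryDataArray>\n',
      '        </binaryDataArrayList>\n',
      '      </spectrum>\n')
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '  <cvList count="3">\n',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>\n',
    '    <cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>\n',
    '    <cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>\n',
    '  </cvList>\n',
    '  <fileDescription>\n',
    '    <fileContent>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="', uuid_str, '"/>\n',
    '    </fileContent>\n',
    '  </fileDescription>\n',
    '  <referenceableParamGroupList count="2">\n',
    '    <referenceableParamGroup id="mzArray">\n',
    '      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '    </referenceableParamGroup>\n',
    '    <referenceableParamGroup id="intensityArray">\n',
    '      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '    </referenceableParamGroup>\n',
    '  </referenceableParamGroupList>\n',
    '  <scanSettingsList count="1">\n',
    '    <scanSettings id="scanSettings1">\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="',
    max(dataset$coords$x) + 1L, '"/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="',
    max(dataset$coords$y) + 1L, '"/>\n',
    '    </scanSettings>\n',
    '  </scanSettingsList>\n',
    '  <softwareList count="1">\n',
    '    <software id="oviMSI" version="0.1.0"/>\n',
    '  </softwareList>\n',
    '  <instrumentConfigurationList count="1">\n',
    '    <instrumentConfiguration id="IC1"/>\n',
    '  </instrumentConfigurationList>\n',
    '  <dataProcessingList count="1">\n',
    '    <dataProcessing id="export">\n',
    '      <processingMethod order="1" softwareRef="oviMSI">\n',
    '        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>\n',
    '      </processingMethod>\n',
    '    </dataProcessing>\n',
    '  </dataProcessingList>\n',
    '  <run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
    '    <spectrumList count="', ns, '" defaultDataProcessingRef="export">\n',
    paste0(spectra, collapse = ""),
    '    </spectrumList>\n',
    '  </run>\n',
    '</mzML>\n')
  writeLines(xml, p$imzml, sep = "")

  jsonlite::write_json(
    list(sample_id = dataset$sample_id, group = dataset$group,
         timepoint = dataset$timepoint, mode = dataset$mode),
    p$sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(p$imzml)
}

format_uuid <- function(bytes) {
  h <- paste(format(bytes), collapse = "")
  paste(substr(h, 1, 8), substr(h, 9, 12), substr(h, 13, 16),
        substr(h, 17, 20), substr(h, 21, 32), sep = "-")
}

#' Read a continuous-mode imzML file
#'
#' Parses the XML index, checks the continuous-mode contract, and reads the
#' shared m/z axis and per-spot intensities from the `.ibd` binary. Study
#' metadata is taken from the JSON sidecar written by [write_imzml()] when
#' present, otherwise from the `metadata` argument.
#'
#' Processed-mode files (one m/z axis per spot) are rejected with an
#' explanatory error rather than silently resampled: every downstream stage
#' assumes a shared axis.
#'
#' @param path Path to the `.imzML` file (the `.ibd` must sit next to it).
#' @param metadata Optional named list overriding/supplying `sample_id`,
#'   `group`, `timepoint`, `mode`.
#' @return An `ion_image_dataset`.
#' @export
read_imzml <- function(path, metadata = NULL) {
  p <- imzml_paths(path)
  if (!file.exists(p$imzml)) stop_ovimsi("imzML file not found: ", p$imzml)
  if (!file.exists(p$ibd))
    stop_ovimsi("binary .ibd companion missing for ", p$imzml)

  doc <- xml2::read_xml(p$imzml)
  xml2::xml_ns_strip(doc)
  acc <- xml2::xml_attr(
    xml2::xml_find_all(doc, "//fileDescription//cvParam"), "accession")
  if (ACC_PROCESSED %in% acc)
    stop_ovimsi("processed-mode imzML (per-spot m/z axes) is not supported; ",
                "this pipeline requires continuous-mode data with one shared axis")
  if (!(ACC_CONTINUOUS %in% acc))
    stop_ovimsi("imzML file does not declare continuous mode")

  # data types per referenceable param group (64- vs 32-bit float)
  sizes <- c("MS:1000523" = 8L, "MS:1000521" = 4L)
  grp_nodes <- xml2::xml_find_all(doc, "//referenceableParamGroup")
  grp_size <- vapply(grp_nodes, function(g) {
    a <- xml2::xml_attr(xml2::xml_find_all(g, ".//cvParam"), "accession")
    hit <- intersect(names(sizes), a)
    if (length(hit)) sizes[[hit[1]]] else 4L
  }, integer(1))
  names(grp_size) <- xml2::xml_attr(grp_nodes, "id")

  spectra <- xml2::xml_find_all(doc, "//spectrum")
  ns <- length(spectra)
  if (ns == 0L) stop_ovimsi("no spectra in imzML")

  get_param <- function(node, accession) {
    xml2::xml_attr(xml2::xml_find_first(
      node, paste0(".//cvParam[@accession='", accession, "']")), "value")
  }
  coords <- data.frame(x = integer(ns), y = integer(ns))
  arrays <- vector("list", ns)
  for (i in seq_len(ns)) {
    sp <- spectra[[i]]
    coords$x[i] <- as.integer(get_param(sp, "IMS:1000050")) - 1L
    coords$y[i] <- as.integer(get_param(sp, "IMS:1000051")) - 1L
    bdas <- xml2::xml_find_all(sp, ".//binaryDataArray")
    info <- lapply(bdas, function(b) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(b, ".//referenceableParamGroupRef"), "ref")
      list(ref = ref,
           offset = as.numeric(get_param(b, "IMS:1000102")),
           length = as.integer(get_param(b, "IMS:1000103")))
    })
    names(info) <- vapply(info, `[[`, character(1), "ref")
    arrays[[i]] <- info
  }

  con <- file(p$ibd, "rb")
  on.exit(close(con))
  read_at <- function(offset, n, size) {
    seek(con, where = offset, origin = "start")
    readBin(con, "numeric", n = n, size = size, endian = "little")
  }
  mz_info <- arrays[[1]][["mzArray"]]
  mz <- read_at(mz_info$offset, mz_info$length, grp_size[["mzArray"]])
  intens <- matrix(0, ns, mz_info$length)
  for (i in seq_len(ns)) {
    ii <- arrays[[i]][["intensityArray"]]
    if (ii$length != mz_info$length)
      stop_ovimsi("spectrum ", i, " violates the shared-axis contract (",
                  ii$length, " vs ", mz_info$length, " channels)")
    intens[i, ] <- read_at(ii$offset, ii$length, grp_size[["intensityArray"]])
  }
  intens[intens < 0] <- 0  # float32 round-off guard

  meta <- list(sample_id = sub("\\.imzML$", "", basename(p$imzml)),
               group = "CTRL", timepoint = "3d", mode = "positive")
  if (file.exists(p$sidecar))
    meta <- utils::modifyList(meta, jsonlite::read_json(p$sidecar))
  if (!is.null(metadata)) meta <- utils::modifyList(meta, metadata)

  ion_image_dataset(meta$sample_id, meta$group, meta$timepoint, meta$mode,
                    coords, mz, intens)
}

#' Write a batch of datasets
#'
#' One imzML/ibd/json triple per dataset, named by `sample_id` and mode.
#'
#' @param datasets List of `ion_image_dataset`.
#' @param dir Output directory (created if needed).
#' @return Character vector of imzML paths, invisibly.
#' @export
write_study_imzml <- function(datasets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(datasets, function(d) {
    write_imzml(d, file.path(dir, paste0(d$sample_id, "_", d$mode, ".imzML")))
  }, character(1))
  invisible(paths)
}
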