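# Minimal mzML support: one centroided spectrum per file, uncompressed
# 64-bit little-endian binary arrays. Enough for interchange with the
# standard toolchain on centroided peak lists; vendor compression schemes
# are out of scope.

#' Read / write a minimal mzML file
#'
#' @param path file path.
#' @return `read_mzml()`: list with numeric vectors `mz` and `intensity`
#'   taken from the first spectrum.
#' @export
read_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "m")
  arrays <- xml2::xml_find_all(doc, ".//m:binaryDataArray", ns)
  if (!length(arrays)) {
    arrays <- xml2::xml_find_all(doc, ".//binaryDataArray")
  }
  if (length(arrays) < 2L) stop("no binary data arrays in ", path,
                                call. = FALSE)
  decode <- function(node) {
    b64 <- xml2::xml_text(xml2::xml_find_first(node, ".//*[local-name()='binary']"))
    raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
    readBin(raw, "double", n = length(raw) %/% 8L, size = 8L,
            endian = "little")
  }
  accs <- vapply(arrays, function(a) {
    params <- xml2::xml_find_all(a, ".//*[local-name()='cvParam']")
    paste(xml2::xml_attr(params, "accession"), collapse = " ")
  }, "")
  mz_i <- grep("MS:1000514", accs)[1]
  int_i <- grep("MS:1000515", accs)[1]
  if (is.na(mz_i) || is.na(int_i)) { mz_i <- 1L; int_i <- 2L }
  list(mz = decode(arrays[[mz_i]]), intensity = decode(arrays[[int_i]]))
}

#' @rdname read_mzml
#' @param x a [peak_list()] or a list with `mz` and `intensity`.
#' @export
write_mzml <- function(x, path) {
  if (inherits(x, "peak_list")) x <- x$peaks
  enc <- function(v) jsonlite::base64_enc(writeBin(as.numeric(v), raw(),
                                                   size = 8L,
                                                   endian = "little"))
  tpl <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    ' <run id="run1"><spectrumList count="1">\n',
    '  <spectrum index="0" id="scan=1" defaultArrayLength="%d">\n',
    '   <cvParam accession="MS:1000127" name="centroid spectrum"/>\n',
    '   <binaryDataArrayList count="2">\n',
    '    <binaryDataArray><cvParam accession="MS:1000514" name="m/z array"/>',
    '<cvParam accession="MS:1000523" name="64-bit float"/>',
    '<cvParam accession="MS:1000576" name="no compression"/>',
    '<binary>%s</binary></binaryDataArray>\n',
    '    <binaryDataArray><cvParam accession="MS:1000515" name="intensity array"/>',
    '<cvParam accession="MS:1000523" name="64-bit float"/>',
    '<cvParam accession="MS:1000576" name="no compression"/>',
    '<binary>%s</binary></binaryDataArray>\n',
    '   </binaryDataArrayList>\n',
    '  </spectrum>\n </spectrumList></run>\n</mzML>\n')
  writeLines(sprintf(tpl, length(x$mz), enc(x$mz), enc(x$intensity)),
             path)
  invisible(path)
}
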