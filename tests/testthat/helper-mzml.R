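# Test-only generator of minimal SRM mzML files (synthetic data), used to
# exercise the mzML chromatogram reader without any binary fixture.

b64 <- function(x, what) {
  raw <- writeBin(x, raw(), size = if (what == "double") 8 else 4,
                  endian = "little")
  gsub("\\n", "", jsonlite::base64_enc(raw))
}
chrom_xml <- function(idx, id, prec, prod, t_min, y) {
  tb <- b64(as.numeric(t_min), "double")
  ib <- b64(as.numeric(y), "double")
  sprintf('
<chromatogram index="%d" id="%s" defaultArrayLength="%d">
  <cvParam cvRef="MS" accession="MS:1001473" name="selected reaction monitoring chromatogram" value=""/>
  <precursor>
    <isolationWindow>
      <cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%.6f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
    </isolationWindow>
    <activation>
      <cvParam cvRef="MS" accession="MS:1000044" name="dissociation method" value=""/>
    </activation>
  </precursor>
  <product>
    <isolationWindow>
      <cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%.6f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
    </isolationWindow>
  </product>
  <binaryDataArrayList count="2">
    <binaryDataArray encodedLength="%d">
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
      <cvParam cvRef="MS" accession="MS:1000595" name="time array" value="" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/>
      <binary>%s</binary>
    </binaryDataArray>
    <binaryDataArray encodedLength="%d">
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>
      <binary>%s</binary>
    </binaryDataArray>
  </binaryDataArrayList>
</chromatogram>', idx, id, length(t_min), prec, prod, nchar(tb), tb, nchar(ib), ib)
}
write_srm_mzml <- function(path, chroms) {
  body <- paste(vapply(seq_along(chroms), function(i) {
    ch <- chroms[[i]]
    chrom_xml(i - 1L, ch$id, ch$prec, ch$prod, ch$t, ch$y)
  }, character(1)), collapse = "\n")
  xml <- sprintf('<?xml version="1.0" encoding="utf-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
  <cvList count="2">
    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>
    <cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>
  </cvList>
  <fileDescription>
    <fileContent>
      <cvParam cvRef="MS" accession="MS:1001473" name="selected reaction monitoring chromatogram" value=""/>
    </fileContent>
  </fileDescription>
  <softwareList count="1">
    <software id="sw" version="0.1">
      <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/>
    </software>
  </softwareList>
  <instrumentConfigurationList count="1">
    <instrumentConfiguration id="IC1">
      <cvParam cvRef="MS" accession="MS:1000870" name="4000 QTRAP" value=""/>
    </instrumentConfiguration>
  </instrumentConfigurationList>
  <dataProcessingList count="1">
    <dataProcessing id="dp">
      <processingMethod order="0" softwareRef="sw">
        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>
      </processingMethod>
    </dataProcessing>
  </dataProcessingList>
  <run id="run1" defaultInstrumentConfigurationRef="IC1">
    <chromatogramList count="%d" defaultDataProcessingRef="dp">%s
    </chromatogramList>
  </run>
</mzML>', length(chroms), body)
  writeLines(xml, path)
}
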