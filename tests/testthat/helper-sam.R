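# Build a tiny coordinate-sorted indexed BAM from SAM text at test time.
write_test_bam <- function(records, chrom = "chrA", chrom_len = 450000L) {
  sam <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  writeLines(c(header, records), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

sam_read <- function(qname, pos, len = 100L, flag = 0L, mapq = 60L,
                     chrom = "chrA") {
  sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
          qname, flag, chrom, pos, mapq, len,
          paste(rep("A", len), collapse = ""))
}
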