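# Shared fixtures: one KB load per run, small builders for observations
# and hand-written VCF text.

KB <- loadKnowledgeBase()

# observation rows for one sample at given KB variants (by rsid), with
# full panel coverage: unmentioned KB positions get dosage 0
obsFor <- function(sample, rsids = character(), dosages = integer(),
        hemizygous = FALSE) {
    v <- kbVariants(KB)
    v <- v[!duplicated(paste(v$chrom, v$pos, v$ref, v$alt)), ]
    d <- integer(nrow(v))
    d[match(rsids, v$rsid)] <- dosages
    data.frame(patient = sample, gene = v$gene, chrom = v$chrom,
        pos = v$pos, ref = v$ref, alt = v$alt, dosage = d,
        hemizygous = hemizygous & v$gene == "G6PD",
        stringsAsFactors = FALSE)
}

# minimal VCF text for given records; coverage asserted over the panel
writeTestVcf <- function(path, samples, records = NULL,
        coverage = TRUE) {
    v <- kbVariants(KB)
    head <- c("##fileformat=VCFv4.2",
        sprintf("##contig=<ID=%s>", unique(v$chrom)))
    if (coverage)
        head <- c(head, sprintf("##coveredregion=%s:%d-%d", v$chrom,
            pmax(1L, v$pos - 100L), v$pos + 100L))
    head <- c(head,
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
    writeLines(c(head, records), path)
    path
}

vcfRecord <- function(chrom, pos, ref, alt, gts) {
    paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# unordered diplotype label for truth-vs-call comparison
dipKey <- function(a1, a2) paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
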