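# VCF reading, normalization, diplotype calling and ambiguity handling.

test_that("variant normalization reaches minimal representation and is idempotent", {
    # suffix then prefix trimming with anchor base kept
    n <- normalizeVariant(100L, "CAG", "CG")
    expect_equal(n, list(pos = 100L, ref = "CA", alt = "C"))
    expect_equal(normalizeVariant(100L, "TCAG", "TCG"),
        list(pos = 101L, ref = "CA", alt = "C"))
    # SNV passes through
    expect_equal(normalizeVariant(5L, "A", "T"),
        list(pos = 5L, ref = "A", alt = "T"))
    # padded insertion collapses to the anchored spelling
    expect_equal(normalizeVariant(10L, "ATT", "ATATT"),
        list(pos = 10L, ref = "A", alt = "ATA"))
    # idempotence over KB spellings and random paddings
    v <- kbVariants(KB)
    for (i in seq_len(nrow(v))) {
        n1 <- normalizeVariant(v$pos[i], v$ref[i], v$alt[i])
        n2 <- do.call(normalizeVariant, n1)
        expect_identical(n1, n2)
    }
})

test_that("VCF genotypes become dosages and coverage governs missingness", {
    tmp <- tempfile(fileext = ".vcf")
    writeTestVcf(tmp, c("S1", "S2", "S3"), vcfRecord("2", 234668879,
        "A", "ATA", c("0/1", "1/1", "0/0")))
    obs <- readVariantCalls(tmp, KB)
    u <- obs[obs$pos == 234668879, ]
    expect_equal(u$dosage[u$patient == "S1"], 1L)
    expect_equal(u$dosage[u$patient == "S2"], 2L)
    expect_equal(u$dosage[u$patient == "S3"], 0L)
    # covered positions with no record are reference
    expect_true(all(obs$dosage[obs$pos != 234668879] == 0L))

    # without a coverage declaration, absent positions are missing
    tmp2 <- tempfile(fileext = ".vcf")
    writeTestVcf(tmp2, "S1", vcfRecord("2", 234668879, "A", "ATA",
        "0/1"), coverage = FALSE)
    obs2 <- readVariantCalls(tmp2, KB)
    expect_equal(obs2$dosage[obs2$pos == 234668879], 1L)
    expect_true(all(is.na(obs2$dosage[obs2$pos != 234668879])))
    # ... unless a coverage mask asserts them
    v <- kbVariants(KB)
    mask <- data.frame(chrom = v$chrom, start = v$pos - 1L,
        end = v$pos + 1L)
    obs3 <- readVariantCalls(tmp2, KB, coverageMask = mask)
    expect_false(anyNA(obs3$dosage))
})

test_that("caller-dialect indel spellings match the KB after normalization", {
    tmp <- tempfile(fileext = ".vcf")
    # *28 insertion padded with trailing reference context
    writeTestVcf(tmp, "S1", vcfRecord("2", 234668879, "AT", "ATAT",
        "0/1"))
    obs <- readVariantCalls(tmp, KB)
    expect_equal(obs$dosage[obs$pos == 234668879 & obs$gene == "UGT1A1"],
        1L)
})

test_that("ploidy inconsistencies warn and mark the observation missing", {
    tmp <- tempfile(fileext = ".vcf")
    writeTestVcf(tmp, "S1", vcfRecord("1", 97915614, "C", "T", "1"))
    expect_warning(obs <- readVariantCalls(tmp, KB), "haploid")
    expect_true(is.na(obs$dosage[obs$pos == 97915614]))
    # haploid X for a declared female sample
    tmp2 <- tempfile(fileext = ".vcf")
    writeTestVcf(tmp2, "S1", vcfRecord("X", 153764217, "C", "T", "1"))
    expect_warning(obs2 <- readVariantCalls(tmp2, KB,
        sex = c(S1 = "Female")), "female")
    expect_true(is.na(obs2$dosage[obs2$pos == 153764217]))
    # malformed file errors
    bad <- tempfile(fileext = ".vcf")
    writeLines("not a vcf at all", bad)
    expect_error(readVariantCalls(bad, KB), "malformed VCF")
})

test_that("single-gene calls cover wild type, het, hom and uncallable cases", {
    # UGT1A1 *28 heterozygote
    r <- callDiplotype("S1", "UGT1A1", obsFor("S1", "rs8175347", 1L), KB)
    expect_equal(r$call$allele2, "*28")
    expect_equal(r$call$carrier_class, "heterozygous")
    expect_false(r$call$ambiguous)
    # homozygote
    r <- callDiplotype("S1", "UGT1A1", obsFor("S1", "rs8175347", 2L), KB)
    expect_equal(dipKey(r$call$allele1, r$call$allele2), "*28/*28")
    expect_equal(r$call$carrier_class, "homozygous_variant")
    # all dosage zero -> reference diplotype
    r <- callDiplotype("S1", "UGT1A1", obsFor("S1"), KB)
    expect_equal(r$call$carrier_class, "wild_type")
    # more than two allele copies has no two-allele explanation: an
    # error state, not a CNV call
    r <- callDiplotype("S1", "TPMT",
        obsFor("S1", c("rs1800460", "rs1142345", "rs1800462"),
            c(2L, 2L, 1L)), KB)
    expect_null(r$call)
    expect_equal(r$uncallable$reason, "no_consistent_diplotype")
    # a *3A homozygote (both component variants at dosage 2) is a
    # legitimate single-candidate call, not an excess-dosage state
    r <- callDiplotype("S1", "TPMT",
        obsFor("S1", c("rs1800460", "rs1142345"), c(2L, 2L)), KB)
    expect_equal(dipKey(r$call$allele1, r$call$allele2), "*3A/*3A")
    # missing observation -> uncallable, never a silent reference call
    obs <- obsFor("S1", "rs1800460", 1L)
    obs$dosage[obs$gene == "TPMT" & obs$pos == 18130918] <- NA
    r <- callDiplotype("S1", "TPMT", obs, KB)
    expect_null(r$call)
    expect_equal(r$uncallable$reason, "missing_observations")
})

test_that("unphased TPMT double heterozygote yields the cis/trans candidate set", {
    obs <- obsFor("S1", c("rs1800460", "rs1142345"), c(1L, 1L))
    r <- callDiplotype("S1", "TPMT", obs, KB)
    expect_true(r$call$ambiguous)
    keys <- dipKey(r$candidates$allele1, r$candidates$allele2)
    expect_setequal(keys, c("*1/*3A", "*3B/*3C"))
    # frequency ranking puts *1/*3A on top: 0.9562*0.0343 >> 0.0027*0.0047
    expect_equal(dipKey(r$call$allele1, r$call$allele2), "*1/*3A")
    expect_equal(sum(r$candidates$weight), 1)
    # the double homozygote also admits a *3B/*3C-homozygote pairing?
    # no: only *3A/*3A explains hom dosages at both sites
    r2 <- callDiplotype("S1", "TPMT",
        obsFor("S1", c("rs1800460", "rs1142345"), c(2L, 2L)), KB)
    expect_false(r2$call$ambiguous)
    expect_equal(dipKey(r2$call$allele1, r2$call$allele2), "*3A/*3A")
})

test_that("ambiguity resolution weights by frequency product with lexicographic ties", {
    cand <- data.frame(allele1 = c("*1", "*3B"),
        allele2 = c("*3A", "*3C"))
    r <- resolveAmbiguity(cand, "TPMT", KB)
    expect_equal(r$allele2[1L], "*3A")
    # weights proportional to products of expected frequencies
    refFreq <- 1 - sum(kbAlleles(KB, "TPMT")$expected_frequency)
    w <- c(refFreq * 0.0343, 0.0027 * 0.0047)
    expect_equal(r$weight, w / sum(w), tolerance = 1e-12)
    # single candidate keeps weight 1
    one <- resolveAmbiguity(data.frame(allele1 = "*1", allele2 = "*2"),
        "TPMT", KB)
    expect_equal(one$weight, 1)
    # exact ties fall back to lexicographic order of the diplotype label
    kb2 <- KB
    kb2@alleles$expected_frequency[kb2@alleles$gene == "TPMT"] <- 0.01
    kb2@cache <- new.env(parent = emptyenv())
    tie <- resolveAmbiguity(data.frame(
        allele1 = c("*3C", "*3B"), allele2 = c("*3B", "*3C")), "TPMT",
        kb2)
    expect_equal(tie$allele1, c("*3B", "*3C"))
})

test_that("panel calls cover every gene exactly once, called or uncallable", {
    pr <- callPanel("S1", obsFor("S1"), KB)
    expect_s4_class(pr, "SamplePanelResult")
    expect_setequal(c(panelCalls(pr)$gene, panelUncallable(pr)$gene),
        kbGenes(KB)$gene)
    expect_equal(nrow(panelCalls(pr)), 15L)
    expect_true(all(panelCalls(pr)$carrier_class == "wild_type"))
    # RYR1 positions missing without coverage -> uncallable
    obs <- obsFor("S1")
    obs$dosage[obs$gene == "RYR1"] <- NA
    pr2 <- callPanel("S1", obs, KB)
    expect_true("RYR1" %in% panelUncallable(pr2)$gene)
    expect_equal(nrow(panelCalls(pr2)), 14L)
})

test_that("male X calls are hemizygous; female X calls diploid", {
    obs <- obsFor("S1", "rs1050828", 1L)
    obs$dosage[obs$gene == "G6PD" & obs$pos == 153763492] <- 1L
    obs$hemizygous[obs$gene == "G6PD" & obs$dosage == 1L] <- TRUE
    pr <- callPanel("S1", obs, KB, sex = "Male")
    g <- panelCalls(pr)[panelCalls(pr)$gene == "G6PD", ]
    expect_equal(g$carrier_class, "hemizygous")
    expect_equal(g$allele1, "A-202A_376G-III")
    # female heterozygote
    obsF <- obsFor("S2")
    obsF$patient <- "S2"
    obsF$dosage[obsF$gene == "G6PD"] <- 1L
    prF <- callPanel("S2", obsF, KB, sex = "Female")
    gF <- panelCalls(prF)[panelCalls(prF)$gene == "G6PD", ]
    expect_equal(gF$carrier_class, "heterozygous")
})
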