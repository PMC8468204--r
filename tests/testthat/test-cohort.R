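# Cohort statistics: tallies, frequencies, Fisher exact, expected-
# frequency comparison, risk matrix.

# independent enumeration oracle for the two-sided Fisher p-value,
# built on log-binomial coefficients (no dhyper)
fisherOracle <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    ks <- max(0L, r1 + c1 - n):min(r1, c1)
    logp <- lchoose(c1, ks) + lchoose(n - c1, r1 - ks) - lchoose(n, r1)
    p <- exp(logp)
    pObs <- exp(lchoose(c1, a) + lchoose(n - c1, r1 - a) -
        lchoose(n, r1))
    min(1, sum(p[p <= pObs * (1 + 1e-7)]))
}

test_that("allele frequencies use the 2N denominator and stay scale-invariant", {
    expect_equal(round(alleleFrequency(23, 134, 0, 291), 4), 0.3093)
    # direct DPYD total; the published table's 0.0240 is the sum of its
    # rounded per-allele rows (display convention, checked elsewhere)
    expect_equal(round(alleleFrequency(0, 14, 0, 291), 4), 0.0241)
    expect_equal(alleleFrequency(0, 0, 0, 291), 0)
    expect_error(alleleFrequency(0, 0, 0, 0), "empty")
    # hemizygous copies count once; published convention divides by 2N
    expect_equal(round(alleleFrequency(0, 0, 1, 291), 4), 0.0017)
    # X-aware alternative uses the chromosome count
    expect_equal(alleleFrequency(0, 0, 1, 291,
        denominator = "x-aware", nMales = 139),
        1 / (2 * 291 - 139))
    # scale invariance
    set.seed(11)
    for (i in 1:20) {
        hom <- sample(0:30, 1); het <- sample(0:100, 1)
        n <- sample(150:400, 1)
        expect_equal(alleleFrequency(hom, het, 0, n),
            alleleFrequency(2 * hom, 2 * het, 0, 2 * n))
    }
})

test_that("allele tallies count carriers without double-counting compound hets", {
    calls <- rbind(
        do.call(rbind, lapply(sprintf("H%02d", 1:3), function(s)
            data.frame(sample = s, gene = "UGT1A1", allele1 = "*28",
                allele2 = "*28", carrier_class = "homozygous_variant",
                ambiguous = FALSE))),
        do.call(rbind, lapply(sprintf("E%02d", 1:5), function(s)
            data.frame(sample = s, gene = "UGT1A1", allele1 = "*1",
                allele2 = "*28", carrier_class = "heterozygous",
                ambiguous = FALSE))),
        data.frame(sample = "C1", gene = "TPMT", allele1 = "*3B",
            allele2 = "*3C", carrier_class = "compound_heterozygous",
            ambiguous = FALSE))
    tal <- tallyAlleles(calls, KB)
    u28 <- tal[tal$gene == "UGT1A1" & tal$allele == "*28", ]
    expect_equal(c(u28$n_hom, u28$n_het), c(3L, 5L))
    # the compound het counts once in the gene total, once per allele row
    expect_equal(tal$n_het[tal$gene == "TPMT" & tal$allele == "*3B"], 1L)
    expect_equal(tal$n_het[tal$gene == "TPMT" & tal$allele == "*3C"], 1L)
    expect_equal(tal$n_carriers[tal$gene == "TPMT" &
        tal$allele == "Total"], 1L)
    # empty cohort of wild types
    wt <- data.frame(sample = "W1", gene = "UGT1A1", allele1 = "*1",
        allele2 = "*1", carrier_class = "wild_type", ambiguous = FALSE)
    talW <- tallyAlleles(wt, KB)
    expect_true(all(talW$n_hom[talW$allele != "Total"] == 0L))
})

test_that("carrier rates count patients with any variant in the gene set", {
    calls <- rbind(
        data.frame(sample = "A", gene = "UGT1A1", allele1 = "*1",
            allele2 = "*28", carrier_class = "heterozygous",
            ambiguous = FALSE),
        data.frame(sample = "A", gene = "DPYD", allele1 = "*1",
            allele2 = "*2A", carrier_class = "heterozygous",
            ambiguous = FALSE),
        data.frame(sample = "B", gene = "UGT1A1", allele1 = "*1",
            allele2 = "*1", carrier_class = "wild_type",
            ambiguous = FALSE))
    expect_equal(carrierRate(calls, "UGT1A1", 2), 0.5)
    expect_equal(carrierRate(calls, c("UGT1A1", "DPYD"), 2), 0.5)
    expect_equal(carrierRate(calls, character(0), 2), 0)
    # published UGT1A1 carrier rate from the landscape counts
    expect_equal(round(157 / 291, 3), 0.540)
})

test_that("two-sided Fisher reproduces the published association p-value", {
    expect_equal(round(fisherExact2x2(7, 2, 13, 23), 4), 0.0567)
    # against the generic implementation in stats
    expect_equal(fisherExact2x2(7, 2, 13, 23),
        stats::fisher.test(matrix(c(7, 2, 13, 23), 2,
            byrow = TRUE))$p.value, tolerance = 1e-12)
    # symmetric null table
    expect_equal(fisherExact2x2(5, 5, 5, 5), 1, tolerance = 1e-12)
    expect_error(fisherExact2x2(0, 0, 3, 4), "degenerate")
    # one-sided and mid-p variants are ordered sensibly
    p2 <- fisherExact2x2(7, 2, 13, 23)
    p1 <- fisherExact2x2(7, 2, 13, 23, variant = "one-sided")
    pm <- fisherExact2x2(7, 2, 13, 23, variant = "mid-p")
    expect_lt(p1, p2)
    expect_lt(pm, p2)
})

test_that("Fisher agrees with the enumeration oracle on all small tables", {
    # exhaustive over every non-degenerate table with N <= 28
    for (n in c(8L, 16L, 28L)) {
        for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
            d <- n - a - b - cc
            if (a + b == 0L || cc + d == 0L || a + cc == 0L ||
                b + d == 0L) next
            expect_equal(fisherExact2x2(a, b, cc, d),
                fisherOracle(a, b, cc, d), tolerance = 1e-12,
                info = paste(a, b, cc, d))
        }
    }
})

test_that("Fisher matches oracle and stats on random tables up to N = 60", {
    set.seed(60)
    for (i in 1:200) {
        n <- sample(4:60, 1)
        repeat {
            x <- as.vector(stats::rmultinom(1, n, rep(0.25, 4)))
            if (x[1] + x[2] > 0 && x[3] + x[4] > 0 &&
                x[1] + x[3] > 0 && x[2] + x[4] > 0) break
        }
        p <- fisherExact2x2(x[1], x[2], x[3], x[4])
        expect_equal(p, fisherOracle(x[1], x[2], x[3], x[4]),
            tolerance = 1e-12)
        expect_equal(p, stats::fisher.test(matrix(x, 2,
            byrow = TRUE))$p.value, tolerance = 1e-9)
        # row swap and column swap leave the two-sided p unchanged
        expect_equal(p, fisherExact2x2(x[3], x[4], x[1], x[2]),
            tolerance = 1e-12)
        expect_equal(p, fisherExact2x2(x[2], x[1], x[4], x[3]),
            tolerance = 1e-12)
    }
})

test_that("expected-frequency comparison flags departures from the binomial CI", {
    # two observed copies against a zero expected frequency
    expect_true(compareExpected(2, 582, 0)$flagged)
    # the common promoter insertion sits inside its interval
    expect_false(compareExpected(180, 582, 0.3165)$flagged)
    # nothing observed, nothing expected
    expect_false(compareExpected(0, 582, 0)$flagged)
    # an expected value far above the observations flags
    expect_true(compareExpected(82, 582, 0.4643)$flagged)
    # the rule is the exact binomial central interval
    ci <- stats::binom.test(180, 582)$conf.int
    cmp <- compareExpected(180, 582, 0.3165)
    expect_equal(c(cmp$ci_low, cmp$ci_high), as.numeric(ci))
})

test_that("toxicity table splits treated units by phenotype and attribution", {
    tox <- data.frame(
        patient = sprintf("P%02d", 1:10),
        drug = c(rep("irinotecan", 6), rep("fluorouracil", 4)),
        gene = c(rep("UGT1A1", 6), rep("DPYD", 4)),
        genotype_related = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE,
            TRUE, FALSE, FALSE, FALSE),
        stringsAsFactors = FALSE)
    ph <- data.frame(
        sample = sprintf("P%02d", 1:10),
        gene = c(rep("UGT1A1", 6), rep("DPYD", 4)),
        phenotype = c("intermediate", "intermediate", "intermediate",
            "normal", "normal", "normal", "intermediate", "normal",
            "normal", "normal"), stringsAsFactors = FALSE)
    ct <- toxicityTable(tox, ph)
    expect_equal(c(ct$a, ct$b, ct$c, ct$d), c(3L, 1L, 1L, 5L))
    # no treated units -> all-zero table
    ct0 <- toxicityTable(tox[0, ], ph)
    expect_equal(c(ct0$a, ct0$b, ct0$c, ct0$d), rep(0L, 4))
})

test_that("cohort summary is deterministic and safe on degenerate inputs", {
    cfg <- defaultCalibration(nPatients = 40, seed = 99)
    co <- generateCohort(cfg, KB)
    vcf <- tempfile(fileext = ".vcf")
    emitVcf(co, vcf, KB)
    sex <- setNames(cohortPatients(co)$gender, cohortPatients(co)$patient)
    res <- callCohort(readVariantCalls(vcf, KB, sex = sex), KB,
        sex = sex)
    s1 <- summarizeCohort(res, cohortPatients(co), cohortTreatments(co),
        KB)
    s2 <- summarizeCohort(res, cohortPatients(co), cohortTreatments(co),
        KB)
    expect_identical(s1$landscape, s2$landscape)
    expect_identical(s1$risk_matrix, s2$risk_matrix)
    expect_identical(s1$fisher_p, s2$fisher_p)
    expect_true(all(s1$risk_matrix$a <= s1$risk_matrix$A))
    # actual risk never exceeds potential risk
    ok <- is.na(s1$risk_matrix$b) | (s1$risk_matrix$b <=
        s1$risk_matrix$a)
    expect_true(all(ok))
    # single-patient cohort: summaries emitted, association skipped
    one <- cohortPatients(co)[1, , drop = FALSE]
    resOne <- res[one$patient]
    sOne <- summarizeCohort(resOne, one,
        cohortTreatments(co)[0, ], KB)
    expect_true(is.na(sOne$fisher_p))
    expect_match(sOne$fisher_note, "not computed")
})
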