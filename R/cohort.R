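## Cohort-level analysis: variant landscape, carrier rates, expected-
## frequency comparison, toxicity contingency table and Fisher's exact
## association.

.bindCalls <- function(panelResults) {
    if (is.data.frame(panelResults)) return(panelResults)
    do.call(rbind, c(lapply(panelResults, panelCalls),
        make.row.names = FALSE))
}

#' Tally allele carriers across a cohort
#'
#' Per (gene, allele): homozygotes carry the allele twice, heterozygotes
#' once (compound heterozygotes count once for each of their two
#' alleles), hemizygotes once on a single X. The per-gene `Total` row
#' counts patients with at least one non-reference allele of the gene --
#' not the sum of the allele rows, so compound heterozygotes are not
#' double-counted.
#'
#' @param panelResults list of
#'   [SamplePanelResult][SamplePanelResult-class] (or the bound calls
#'   data.frame).
#' @param kb a KnowledgeBase.
#' @return data.frame: gene, allele ("Total" rows included), n_hom,
#'   n_het, n_hemi, n_carriers, n_patients_total.
#' @export
tallyAlleles <- function(panelResults, kb) {
    calls <- .bindCalls(panelResults)
    nTotal <- length(unique(calls$sample))
    out <- list()
    for (gene in kb@genes$gene) {
        refName <- kb@genes$reference_allele[kb@genes$gene == gene]
        gc <- calls[calls$gene == gene, , drop = FALSE]
        for (al in kbAlleles(kb, gene)$allele) {
            hemi <- gc$carrier_class == "hemizygous" & gc$allele1 == al
            hom <- !hemi & gc$allele1 == al & gc$allele2 == al
            het <- !hemi & !hom & (gc$allele1 == al | gc$allele2 == al)
            out[[length(out) + 1L]] <- data.frame(gene = gene,
                allele = al, n_hom = sum(hom), n_het = sum(het),
                n_hemi = sum(hemi), n_carriers = sum(hom | het | hemi),
                n_patients_total = nTotal, stringsAsFactors = FALSE)
        }
        carriers <- sum(!gc$carrier_class %in% "wild_type")
        out[[length(out) + 1L]] <- data.frame(gene = gene,
            allele = "Total", n_hom = NA_integer_, n_het = NA_integer_,
            n_hemi = NA_integer_, n_carriers = carriers,
            n_patients_total = nTotal, stringsAsFactors = FALSE)
    }
    do.call(rbind, c(out, make.row.names = FALSE))
}

#' Allele frequency under the uniform 2N denominator
#'
#' (2 x homozygotes + heterozygotes + hemizygotes) / (2 x patients).
#' The default denominator is 2N for every gene, X-linked ones included
#' (reproducing the published convention); the X-aware alternative uses
#' 2 x females + males chromosomes for X-linked genes.
#'
#' @param nHom,nHet,nHemi genotype counts.
#' @param nPatients cohort size (> 0).
#' @param denominator "2n" (default) or "x-aware".
#' @param nMales number of male patients (used only by "x-aware").
#' @return frequency in \[0, 1\] (full precision; display rounding to 4
#'   decimals is the caller's concern).
#' @examples
#' round(alleleFrequency(23, 134, 0, 291), 4)  # 0.3093
#' @export
alleleFrequency <- function(nHom, nHet, nHemi = 0, nPatients,
        denominator = c("2n", "x-aware"), nMales = 0) {
    denominator <- match.arg(denominator)
    if (nPatients <= 0) stop("empty cohort")
    denom <- if (denominator == "2n") 2 * nPatients else
        2 * nPatients - nMales
    (2 * nHom + nHet + nHemi) / denom
}

#' Fraction of patients carrying any variant in a gene set
#'
#' @param panelResults list of SamplePanelResult or bound calls
#'   data.frame.
#' @param genes character vector of gene symbols ("any" panel = all KB
#'   genes); empty set gives 0.
#' @param nPatients cohort size (defaults to the number of distinct
#'   samples in the calls).
#' @return proportion in \[0, 1\].
#' @export
carrierRate <- function(panelResults, genes, nPatients = NULL) {
    calls <- .bindCalls(panelResults)
    if (is.null(nPatients)) nPatients <- length(unique(calls$sample))
    if (length(genes) == 0L || nPatients == 0L) return(0)
    hit <- calls$gene %in% genes & !calls$carrier_class %in% "wild_type"
    length(unique(calls$sample[hit])) / nPatients
}

#' Fraction of patients with a variant relevant to their own disease
#'
#' A patient counts when they carry at least one non-reference allele
#' in a gene linked, through the indication matrix, to a drug indicated
#' for their primary site (any tier). This is the "disease-relevant
#' carrier" rate of the cohort.
#'
#' @param patients data.frame with patient and primary_site.
#' @param calls bound calls data.frame (columns sample or patient,
#'   gene, carrier_class) -- pipeline calls and generator ground truth
#'   both fit.
#' @param kb a KnowledgeBase.
#' @return proportion in \[0, 1\].
#' @export
diseaseRelevantCarrierRate <- function(patients, calls, kb) {
    if (nrow(patients) == 0L) return(0)
    idCol <- if ("sample" %in% names(calls)) "sample" else "patient"
    rules <- unique(kbIndicationRules(kb)[, c("disease", "gene")])
    site <- canonicalDisease(kb, patients$primary_site)
    car <- calls[!calls$carrier_class %in% "wild_type", , drop = FALSE]
    carKey <- paste(car[[idCol]], car$gene)
    rel <- merge(data.frame(patient = patients$patient,
        disease = site, stringsAsFactors = FALSE), rules,
        by = "disease")
    hitPatients <- unique(rel$patient[
        paste(rel$patient, rel$gene) %in% carKey])
    length(hitPatients) / nrow(patients)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value by summation over the hypergeometric distribution of
#' the first cell given fixed margins. The two-sided value follows the
#' small-p-values definition: the sum of the probabilities of all tables
#' no more probable than the observed one (with the customary relative
#' tolerance on the equality comparison). Mid-p and one-sided variants
#' are available but non-default.
#'
#' @param a,b,c,d cell counts, rows = variant carrier / wild type,
#'   columns = toxicity / no toxicity.
#' @param variant "two-sided" (default), "mid-p", or "one-sided"
#'   (alternative of enrichment in cell `a`).
#' @return p-value in (0, 1].
#' @examples
#' round(fisherExact2x2(7, 2, 13, 23), 4)  # 0.0567
#' @export
fisherExact2x2 <- function(a, b, c, d,
        variant = c("two-sided", "mid-p", "one-sided")) {
    variant <- match.arg(variant)
    if (any(c(a, b, c, d) < 0)) stop("negative cell count")
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    if (r1 == 0L || c1 == 0L || r1 == n || c1 == n)
        stop("degenerate margins: every margin must be positive")
    kRange <- max(0L, r1 + c1 - n):min(r1, c1)
    dens <- stats::dhyper(kRange, c1, n - c1, r1)
    dObs <- stats::dhyper(a, c1, n - c1, r1)
    relEps <- 1 + 1e-7
    switch(variant,
        "two-sided" = min(1, sum(dens[dens <= dObs * relEps])),
        "mid-p" = min(1, sum(dens[dens < dObs / relEps]) +
            0.5 * sum(dens[dens <= dObs * relEps &
                dens >= dObs / relEps])),
        "one-sided" = min(1, sum(dens[kRange >= a])))
}

#' Compare an observed allele frequency with its expected value
#'
#' Operationalizes "similar to expected" as containment of the expected
#' population frequency in the exact binomial central 95% confidence
#' interval of the observed allele count; a zero expected frequency is
#' flagged by any observation.
#'
#' @param nObserved observed allele copies.
#' @param nAlleles total allele copies screened (2N under the default
#'   denominator).
#' @param expected expected population frequency (KB value).
#' @param source frequency source tag (CPIC/gnomAD/ExAC), carried
#'   through.
#' @param level confidence level of the binomial interval.
#' @return one-row data.frame: observed_frequency, expected_frequency,
#'   source, ci_low, ci_high, flagged.
#' @export
compareExpected <- function(nObserved, nAlleles, expected,
        source = NA_character_, level = 0.95) {
    ci <- stats::binom.test(nObserved, nAlleles,
        conf.level = level)$conf.int
    flagged <- (expected == 0 && nObserved > 0) ||
        expected < ci[1L] || expected > ci[2L]
    data.frame(observed_frequency = nObserved / nAlleles,
        expected_frequency = expected, source = source,
        ci_low = ci[1L], ci_high = ci[2L], flagged = flagged,
        stringsAsFactors = FALSE)
}

#' Build the genotype-by-toxicity 2x2 contingency table
#'
#' Units are treated (patient, drug) courses of toxicity-associated
#' anti-cancer drugs. Row 1 collects units where the patient's phenotype
#' for the drug's gene is non-normal (intermediate/poor), row 2 the
#' normal-metabolizer units; column 1 counts genotype-related toxicity.
#'
#' @param toxicityCalls data.frame from [attributeCohortToxicity()].
#' @param phenotypes data.frame with sample, gene, phenotype covering
#'   the treated patients.
#' @return list(a, b, c, d, table) -- `table` is the 2x2 matrix.
#' @export
toxicityTable <- function(toxicityCalls, phenotypes) {
    if (nrow(toxicityCalls) == 0L)
        return(list(a = 0L, b = 0L, c = 0L, d = 0L,
            table = matrix(0L, 2L, 2L)))
    ph <- phenotypes$phenotype[match(
        paste(toxicityCalls$patient, toxicityCalls$gene),
        paste(phenotypes$sample, phenotypes$gene))]
    variantRow <- ph %in% c("intermediate", "poor")
    tox <- toxicityCalls$genotype_related
    a <- sum(variantRow & tox); b <- sum(variantRow & !tox)
    cc <- sum(!variantRow & tox); d <- sum(!variantRow & !tox)
    m <- matrix(c(a, b, cc, d), nrow = 2L, byrow = TRUE,
        dimnames = list(c("variant", "wild_type"),
            c("toxicity", "no_toxicity")))
    list(a = a, b = b, c = cc, d = d, table = m)
}

#' Potential/actual risk matrix over a cohort
#'
#' Reproduces the published risk-matrix layout: per (gene, drug,
#' disease, tier), `a` = patients with any disease-relevant variant
#' (potential risk), `A` = all patients with the disease, `b` = variant
#' carriers treated with the drug at the institution, `B` = variant
#' carriers with the disease excluding patients treated elsewhere.
#' `b`/`B` are NA when no carrier was treated on site.
#'
#' @param patients patient data.frame (patient, primary_site).
#' @param findingsPotential bound potential findings for the cohort.
#' @param treatments treatment data.frame (patient, drug,
#'   received_here); NULL when only potential risk is of interest.
#' @param kb a KnowledgeBase.
#' @return data.frame: gene, drug, disease, tier, a, A, b, B.
#' @export
riskMatrix <- function(patients, findingsPotential, treatments = NULL,
        kb) {
    rules <- kbIndicationRules(kb)
    site <- canonicalDisease(kb, patients$primary_site)
    elsewhere <- if (is.null(treatments)) character() else
        unique(treatments$patient[!treatments$received_here])
    out <- lapply(seq_len(nrow(rules)), function(i) {
        r <- rules[i, ]
        inDisease <- patients$patient[site == r$disease]
        f <- findingsPotential[findingsPotential$disease == r$disease &
            findingsPotential$drug == r$drug, , drop = FALSE]
        carriers <- unique(f$patient)
        a <- length(carriers); A <- length(inDisease)
        if (is.null(treatments)) {
            b <- NA_integer_; B <- NA_integer_
        } else {
            onSite <- setdiff(carriers, elsewhere)
            B <- length(onSite)
            here <- treatments[treatments$received_here %in% TRUE &
                treatments$drug == r$drug, , drop = FALSE]
            b <- length(intersect(onSite, here$patient))
            if (B == 0L) { b <- NA_integer_; B <- NA_integer_ }
        }
        data.frame(gene = r$gene, drug = r$drug, disease = r$disease,
            tier = r$tier, a = a, A = A, b = b, B = B,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, make.row.names = FALSE))
}

#' Cohort summary: landscape, risk matrix, toxicity and association
#'
#' Deterministic tabular outputs mirroring the published analyses: the
#' variant landscape (tallies, frequencies, expected-frequency
#' comparison), the risk matrix, the genotype-by-toxicity tallies, and
#' the two-sided Fisher exact association (skipped with a note when the
#' contingency table is degenerate).
#'
#' @param panelResults list of SamplePanelResult for the cohort.
#' @param patients patient data.frame.
#' @param treatments treatment data.frame (may have zero rows).
#' @param kb a KnowledgeBase.
#' @param fisherVariant passed to [fisherExact2x2()].
#' @return list: landscape, carrier_rate_any, risk_matrix,
#'   toxicity_calls, contingency, fisher_p (NA when not computed),
#'   fisher_note.
#' @export
summarizeCohort <- function(panelResults, patients, treatments, kb,
        fisherVariant = "two-sided") {
    calls <- .bindCalls(panelResults)
    nPatients <- nrow(patients)
    tal <- tallyAlleles(panelResults, kb)
    al <- kbAlleles(kb)
    isTotal <- tal$allele == "Total"
    freq <- ifelse(isTotal, NA_real_, mapply(alleleFrequency,
        tal$n_hom, tal$n_het, tal$n_hemi,
        MoreArgs = list(nPatients = nPatients)))
    ## display convention: gene totals are the sum of the rounded
    ## per-allele rows, as in the published landscape table
    disp <- round(freq, 4L)
    disp[isTotal] <- vapply(tal$gene[isTotal], function(g)
        sum(disp[tal$gene == g & !isTotal]), numeric(1L))
    expected <- al$expected_frequency[match(
        paste(tal$gene, tal$allele), paste(al$gene, al$allele))]
    landscape <- cbind(tal,
        frequency = disp, expected_frequency = expected)

    phenotypes <- do.call(rbind, c(lapply(panelResults, phenotypePanel,
        kb = kb), make.row.names = FALSE))
    site <- canonicalDisease(kb, patients$primary_site)
    fnd <- list()
    for (i in seq_len(nrow(patients))) {
        p <- patients[i, ]
        pc <- calls[calls$sample == p$patient, , drop = FALSE]
        names(pc)[names(pc) == "sample"] <- "patient"
        if (p$primary_site %in% kb@indicationRules$disease ||
            canonicalDisease(kb, p$primary_site) %in%
                kb@indicationRules$disease)
            fnd[[i]] <- potentialRisk(p, pc, kb,
                phenotypes = phenotypes[
                    phenotypes$sample == p$patient, , drop = FALSE])
    }
    findings <- if (length(fnd)) do.call(rbind, c(fnd,
        make.row.names = FALSE)) else .emptyFindings()

    rm <- riskMatrix(patients, findings, treatments, kb)
    tox <- attributeCohortToxicity(treatments, kb)
    ct <- toxicityTable(tox, phenotypes)
    degenerate <- (ct$a + ct$b) == 0L || (ct$c + ct$d) == 0L ||
        (ct$a + ct$c) == 0L || (ct$b + ct$d) == 0L
    fisherP <- if (degenerate) NA_real_ else
        fisherExact2x2(ct$a, ct$b, ct$c, ct$d, variant = fisherVariant)
    list(landscape = landscape,
        carrier_rate_any = carrierRate(calls, kb@genes$gene, nPatients),
        risk_matrix = rm,
        findings = findings,
        toxicity_calls = tox,
        contingency = ct,
        fisher_p = fisherP,
        fisher_note = if (degenerate)
            "association not computed: degenerate contingency table"
            else sprintf("two-sided Fisher exact p = %.4f", fisherP))
}
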