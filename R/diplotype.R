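## Diplotype calling: VCF -> genotype observations -> per-gene star-allele
## diplotypes, with explicit unphased multi-variant ambiguity.

#' SamplePanelResult: one sample's calls over the whole panel
#'
#' @slot sample sample id.
#' @slot calls data.frame with one row per callable gene: gene, allele1,
#'   allele2, carrier_class (wild_type / heterozygous /
#'   homozygous_variant / compound_heterozygous / hemizygous), ambiguous.
#' @slot candidates named list (by gene) of data.frames allele1, allele2,
#'   weight -- the full ranked candidate set where the unphased genotype
#'   admits more than one diplotype.
#' @slot uncallable data.frame: gene, reason.
#' @export
setClass("SamplePanelResult",
    representation(sample = "character", calls = "data.frame",
        candidates = "list", uncallable = "data.frame"))

setValidity("SamplePanelResult", function(object) {
    both <- intersect(object@calls$gene, object@uncallable$gene)
    if (length(both) > 0L)
        return(paste("gene both called and uncallable:",
            paste(both, collapse = ", ")))
    TRUE
})

#' @describeIn SamplePanelResult-class compact summary
#' @param object a SamplePanelResult
#' @export
setMethod("show", "SamplePanelResult", function(object) {
    cat("SamplePanelResult", object@sample, "--",
        nrow(object@calls), "genes called,",
        sum(object@calls$ambiguous), "ambiguous,",
        nrow(object@uncallable), "uncallable\n")
    invisible(NULL)
})

#' @rdname SamplePanelResult-class
#' @param x a SamplePanelResult
#' @export
panelCalls <- function(x) x@calls

#' @rdname SamplePanelResult-class
#' @export
panelCandidates <- function(x) x@candidates

#' @rdname SamplePanelResult-class
#' @export
panelUncallable <- function(x) x@uncallable

## variant normalization ----------------------------------------------

#' Normalize a variant to minimal representation
#'
#' Trims the common suffix, then the common prefix (advancing the
#' position), always keeping at least one base of ref and alt -- the
#' standard minimal-representation rule used before matching caller
#' output against the knowledge base's canonical left-aligned spellings.
#'
#' @param pos 1-based position.
#' @param ref,alt allele strings.
#' @return list(pos, ref, alt).
#' @export
normalizeVariant <- function(pos, ref, alt) {
    r <- strsplit(ref, "")[[1L]]; a <- strsplit(alt, "")[[1L]]
    while (length(r) > 1L && length(a) > 1L &&
           r[length(r)] == a[length(a)]) {
        r <- r[-length(r)]; a <- a[-length(a)]
    }
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
        r <- r[-1L]; a <- a[-1L]; pos <- pos + 1L
    }
    list(pos = as.integer(pos), ref = paste(r, collapse = ""),
        alt = paste(a, collapse = ""))
}

## per-gene dosage lookup tables --------------------------------------

## Enumerates every unordered allele pair (reference included) of a gene
## and indexes them by the implied dosage vector over the gene's unique
## defining variants. Cached in kb@cache.
geneDosageTable <- function(kb, gene) {
    key <- paste0("dose:", gene)
    if (!is.null(kb@cache[[key]])) return(kb@cache[[key]])
    vr <- kbVariants(kb, gene)
    vid <- unique(.variantId(vr$chrom, vr$pos, vr$ref, vr$alt))
    vid <- sort(vid)
    refName <- kb@genes$reference_allele[kb@genes$gene == gene]
    alleles <- unique(vr$allele)
    M <- matrix(0L, nrow = length(alleles) + 1L, ncol = length(vid),
        dimnames = list(c(refName, alleles), vid))
    for (al in alleles) {
        w <- vr$allele == al
        M[al, .variantId(vr$chrom[w], vr$pos[w], vr$ref[w], vr$alt[w])] <- 1L
    }
    dip <- new.env(parent = emptyenv())
    nm <- rownames(M)
    for (i in seq_along(nm)) for (j in i:length(nm)) {
        k <- paste(M[i, ] + M[j, ], collapse = "|")
        pair <- data.frame(allele1 = nm[i], allele2 = nm[j],
            stringsAsFactors = FALSE)
        dip[[k]] <- rbind(dip[[k]], pair)
    }
    hap <- new.env(parent = emptyenv())
    for (i in seq_along(nm)) {
        k <- paste(M[i, ], collapse = "|")
        one <- data.frame(allele1 = nm[i], allele2 = nm[i],
            stringsAsFactors = FALSE)
        hap[[k]] <- rbind(hap[[k]], one)
    }
    tab <- list(gene = gene, variantIds = vid, reference = refName,
        membership = M, diploid = dip, haploid = hap)
    kb@cache[[key]] <- tab
    tab
}

## GT string -> dosage of allele index `idx`; returns c(dosage, ploidy)
gtDosage <- function(gt, idx = 1L) {
    if (is.na(gt) || gt %in% c(".", "./.", ".|."))
        return(c(NA_integer_, NA_integer_))
    parts <- strsplit(gt, "[/|]")[[1L]]
    if (any(parts == "."))
        return(c(NA_integer_, length(parts)))
    c(sum(parts == as.character(idx)), length(parts))
}

## coverage declarations: ##coveredregion=chr:start-end (or "all")
parseCoveredRegions <- function(meta) {
    lines <- grep("^##coveredregion=", meta, value = TRUE)
    vals <- sub("^##coveredregion=", "", lines)
    if (any(vals == "all")) return("all")
    if (length(vals) == 0L)
        return(data.frame(chrom = character(), start = integer(),
            end = integer()))
    m <- regmatches(vals, regexec("^([^:]+):([0-9]+)-([0-9]+)$", vals))
    ok <- lengths(m) == 4L
    do.call(rbind, lapply(m[ok], function(x)
        data.frame(chrom = x[2L], start = as.integer(x[3L]),
            end = as.integer(x[4L]), stringsAsFactors = FALSE)))
}

isCovered <- function(chrom, pos, regions) {
    if (identical(regions, "all")) return(rep(TRUE, length(chrom)))
    if (is.null(regions) || nrow(regions) == 0L)
        return(rep(FALSE, length(chrom)))
    vapply(seq_along(chrom), function(i)
        any(regions$chrom == chrom[i] & regions$start <= pos[i] &
            regions$end >= pos[i]), logical(1L))
}

#' Read per-sample genotype observations from a VCF
#'
#' Retains only positions matching knowledge-base variant keys (after
#' minimal-representation normalization) and converts GT fields to
#' alternate-allele dosages. A KB position absent from the VCF records is
#' dosage 0 only when the position lies inside a covered region declared
#' in the header (`##coveredregion=chr:start-end` or
#' `##coveredregion=all`) or in `coverageMask`; otherwise it is marked
#' missing (`NA` dosage) -- absence of evidence is not a reference call.
#'
#' @param vcfPath path to a VCF 4.x file (single- or multi-sample).
#' @param kb a KnowledgeBase.
#' @param sex optional named character vector (by sample); samples whose
#'   value is not `"Female"` are treated as hemizygous on X-linked genes.
#' @param coverageMask optional data.frame(chrom, start, end) asserting
#'   covered regions in addition to the VCF header declaration.
#' @return data.frame: patient, gene, chrom, pos, ref, alt, dosage
#'   (NA = missing), hemizygous.
#' @export
readVariantCalls <- function(vcfPath, kb, sex = NULL,
        coverageMask = NULL) {
    vcf <- tryCatch(vcfR::read.vcfR(vcfPath, verbose = FALSE),
        error = function(e) stop("malformed VCF '", vcfPath, "': ",
            conditionMessage(e), call. = FALSE))
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
        dimnames = list(NULL, names(fix)))
    nRec <- nrow(fix)
    samples <- colnames(vcf@gt)[-1L]
    if (nRec > 0L) {
        gt <- vcfR::extract.gt(vcf, element = "GT")
        if (is.null(dim(gt)))
            gt <- matrix(gt, nrow = nRec,
                dimnames = list(NULL, samples))
    } else {
        gt <- matrix(character(), 0L, length(samples),
            dimnames = list(NULL, samples))
    }

    kbv <- kb@variants
    kbId <- .variantId(kbv$chrom, kbv$pos, kbv$ref, kbv$alt)
    kbUnique <- !duplicated(kbId)
    kbTab <- data.frame(gene = kbv$gene[kbUnique],
        chrom = kbv$chrom[kbUnique], pos = kbv$pos[kbUnique],
        ref = kbv$ref[kbUnique], alt = kbv$alt[kbUnique],
        id = kbId[kbUnique], stringsAsFactors = FALSE)

    regions <- parseCoveredRegions(vcf@meta)
    if (!is.null(coverageMask) && !identical(regions, "all")) {
        if (is.character(coverageMask) && identical(coverageMask, "all"))
            regions <- "all"
        else regions <- rbind(regions, coverageMask)
    }
    covered <- isCovered(kbTab$chrom, kbTab$pos, regions)

    mode <- kb@genes$chromosome_mode[match(kbTab$gene, kb@genes$gene)]
    isFemale <- function(s) {
        if (is.null(sex)) NA else identical(unname(sex[s]), "Female")
    }

    ## map VCF records (normalized, per ALT allele) onto KB keys
    recMap <- vector("list", nRec)
    if (nRec > 0L) for (i in seq_len(nRec)) {
        alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
        for (ai in seq_along(alts)) {
            nv <- normalizeVariant(as.integer(fix[i, "POS"]),
                fix[i, "REF"], alts[ai])
            id <- .variantId(fix[i, "CHROM"], nv$pos, nv$ref, nv$alt)
            k <- match(id, kbTab$id)
            if (!is.na(k))
                recMap[[i]] <- rbind(recMap[[i]],
                    data.frame(kbIdx = k, altIdx = ai))
        }
    }

    out <- vector("list", length(samples))
    for (si in seq_along(samples)) {
        s <- samples[si]
        dosage <- ifelse(covered, 0L, NA_integer_)
        hemi <- rep(FALSE, nrow(kbTab))
        for (i in seq_len(nRec)) {
            mp <- recMap[[i]]
            if (is.null(mp)) next
            for (r in seq_len(nrow(mp))) {
                k <- mp$kbIdx[r]
                dp <- gtDosage(gt[i, s], mp$altIdx[r])
                xg <- mode[k] == "x_linked"
                fem <- isFemale(s)
                if (!is.na(dp[2L])) {
                    if (dp[2L] == 1L && !xg) {
                        warning("sample ", s, ": haploid GT at autosomal ",
                            kbTab$id[k], "; marked missing")
                        dosage[k] <- NA_integer_
                        next
                    }
                    if (dp[2L] == 1L && xg && isTRUE(fem)) {
                        warning("sample ", s, ": haploid GT on X for a ",
                            "female sample at ", kbTab$id[k],
                            "; marked missing")
                        dosage[k] <- NA_integer_
                        next
                    }
                    if (dp[2L] == 2L && xg && identical(fem, FALSE)) {
                        warning("sample ", s, ": diploid GT on X for a ",
                            "male sample at ", kbTab$id[k],
                            "; marked missing")
                        dosage[k] <- NA_integer_
                        next
                    }
                    if (dp[2L] == 1L && xg) hemi[k] <- TRUE
                }
                dosage[k] <- dp[1L]
            }
        }
        ## covered-but-absent X positions for male samples are
        ## hemizygous reference
        maleX <- mode == "x_linked" & !is.na(dosage) &
            identical(isFemale(s), FALSE)
        hemi[maleX] <- TRUE
        out[[si]] <- data.frame(patient = s, gene = kbTab$gene,
            chrom = kbTab$chrom, pos = kbTab$pos, ref = kbTab$ref,
            alt = kbTab$alt, dosage = dosage, hemizygous = hemi,
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

## ambiguity resolution -----------------------------------------------

#' Rank alternative diplotype candidates by population frequency
#'
#' Weights each candidate diplotype by the product of its two alleles'
#' expected population frequencies (the reference allele's frequency is
#' one minus the sum of the gene's variant-allele frequencies, floored at
#' zero), normalizes the weights to sum to one, and orders by decreasing
#' weight with a deterministic lexicographic tie-break on the
#' "allele1/allele2" string. The call itself never discards candidates:
#' the full ranked set travels with the call.
#'
#' @param candidates data.frame(allele1, allele2).
#' @param gene gene symbol.
#' @param kb a KnowledgeBase.
#' @return `candidates` with a `weight` column, ranked.
#' @export
resolveAmbiguity <- function(candidates, gene, kb) {
    al <- kbAlleles(kb, gene)
    refName <- kb@genes$reference_allele[kb@genes$gene == gene]
    refFreq <- max(0, 1 - sum(al$expected_frequency))
    freqOf <- function(name) ifelse(name == refName, refFreq,
        al$expected_frequency[match(name, al$allele)])
    w <- freqOf(candidates$allele1) * freqOf(candidates$allele2)
    if (sum(w) > 0) w <- w / sum(w)
    else w <- rep(1 / length(w), length(w))
    lab <- paste(candidates$allele1, candidates$allele2, sep = "/")
    ord <- order(-w, lab)
    out <- candidates[ord, , drop = FALSE]
    out$weight <- w[ord]
    rownames(out) <- NULL
    out
}

## single-gene call from a dosage vector ------------------------------

.carrierClass <- function(a1, a2, refName, hemi) {
    if (hemi) return(if (a1 == refName) "wild_type" else "hemizygous")
    if (a1 == refName && a2 == refName) return("wild_type")
    if (a1 == refName || a2 == refName) return("heterozygous")
    if (a1 == a2) return("homozygous_variant")
    "compound_heterozygous"
}

#' Call one gene's diplotype from variant dosages
#'
#' Enumerates every assignment of the observed variant dosages to an
#' unordered pair of knowledge-base alleles. A single consistent
#' assignment is returned unambiguous; several (the unphased cis/trans
#' case, e.g. TPMT c.460G>A het + c.719A>G het admitting *1/*3A and
#' *3B/*3C) are ranked by [resolveAmbiguity()] and flagged, with the full
#' candidate list preserved. Missing observations among the gene's
#' defining variants make the gene uncallable (never a silent reference
#' call), as does a total autosomal dosage above two.
#'
#' @param sample sample id.
#' @param gene gene symbol.
#' @param observations data.frame as from [readVariantCalls()],
#'   restricted or not to the gene (it is filtered internally).
#' @param kb a KnowledgeBase.
#' @param hemizygous call the gene haploid (male X).
#' @return list(call = one-row data.frame or NULL, candidates =
#'   data.frame or NULL, uncallable = reason string or NULL).
#' @export
callDiplotype <- function(sample, gene, observations, kb,
        hemizygous = FALSE) {
    tab <- geneDosageTable(kb, gene)
    obs <- observations[observations$patient == sample &
        observations$gene == gene, , drop = FALSE]
    dose <- rep(NA_integer_, length(tab$variantIds))
    names(dose) <- tab$variantIds
    if (nrow(obs) > 0L) {
        id <- .variantId(obs$chrom, obs$pos, obs$ref, obs$alt)
        keep <- id %in% tab$variantIds
        dose[id[keep]] <- obs$dosage[keep]
        if (any(obs$hemizygous[keep])) hemizygous <- TRUE
    }
    .callFromDosage(sample, gene, dose, kb, hemizygous)
}

.callFromDosage <- function(sample, gene, dose, kb, hemizygous) {
    tab <- geneDosageTable(kb, gene)
    un <- function(reason) list(call = NULL, candidates = NULL,
        uncallable = data.frame(gene = gene, reason = reason,
            stringsAsFactors = FALSE))
    if (anyNA(dose)) return(un("missing_observations"))
    ## consistency (at most two allele copies, haploid on male X) is
    ## enforced by the enumeration itself: an observed dosage vector
    ## outside the table has no two-allele explanation
    cand <- if (hemizygous) tab$haploid[[paste(dose, collapse = "|")]]
        else tab$diploid[[paste(dose, collapse = "|")]]
    if (is.null(cand)) return(un("no_consistent_diplotype"))
    cand <- resolveAmbiguity(cand, gene, kb)
    top <- cand[1L, ]
    call <- data.frame(sample = sample, gene = gene,
        allele1 = top$allele1, allele2 = top$allele2,
        carrier_class = .carrierClass(top$allele1, top$allele2,
            tab$reference, hemizygous),
        ambiguous = nrow(cand) > 1L, stringsAsFactors = FALSE)
    list(call = call,
        candidates = if (nrow(cand) > 1L) cand else NULL,
        uncallable = NULL)
}

#' Call the full panel for one sample
#'
#' Applies [callDiplotype()] to every knowledge-base gene. Genes whose
#' defining variants carry missing observations land in the `uncallable`
#' table with a reason.
#'
#' @inheritParams callDiplotype
#' @param sex optional sample sex label; non-`"Female"` values make
#'   X-linked genes haploid.
#' @return a [SamplePanelResult][SamplePanelResult-class].
#' @export
callPanel <- function(sample, observations, kb, sex = NULL) {
    calls <- list(); cands <- list(); unc <- list()
    for (gene in kb@genes$gene) {
        hemi <- kb@genes$chromosome_mode[kb@genes$gene == gene] ==
            "x_linked" && !is.null(sex) && !identical(sex, "Female")
        res <- callDiplotype(sample, gene, observations, kb,
            hemizygous = hemi)
        if (!is.null(res$call)) {
            calls[[gene]] <- res$call
            if (!is.null(res$candidates))
                cands[[gene]] <- res$candidates
        } else unc[[gene]] <- res$uncallable
    }
    new("SamplePanelResult", sample = sample,
        calls = if (length(calls)) do.call(rbind, c(calls,
            make.row.names = FALSE)) else
            data.frame(sample = character(), gene = character(),
                allele1 = character(), allele2 = character(),
                carrier_class = character(), ambiguous = logical()),
        candidates = cands,
        uncallable = if (length(unc)) do.call(rbind, c(unc,
            make.row.names = FALSE)) else
            data.frame(gene = character(), reason = character()))
}

#' Call the panel for every sample of a cohort
#'
#' Vectorized multi-sample driver over the same per-gene dosage lookup
#' tables as [callPanel()].
#'
#' @param observations long data.frame from [readVariantCalls()].
#' @param kb a KnowledgeBase.
#' @param sex optional named character vector by sample.
#' @return named list of [SamplePanelResult][SamplePanelResult-class].
#' @export
callCohort <- function(observations, kb, sex = NULL) {
    samples <- unique(observations$patient)
    obsBy <- split(observations, observations$patient)
    out <- vector("list", length(samples))
    names(out) <- samples
    for (s in samples) {
        sx <- if (is.null(sex)) NULL else unname(sex[s])
        out[[s]] <- callPanel(s, obsBy[[s]], kb, sex = sx)
    }
    out
}
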