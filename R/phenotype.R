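## Diplotype -> CPIC metabolizer phenotype / activity score.

#' CPIC activity score of a diplotype
#'
#' Sum of the two alleles' activity values (reference allele 1.0) for
#' genes using the activity-score phenotype rule (DPYD, CYP2D6).
#'
#' @param gene gene symbol with the `activity_score` rule.
#' @param allele1,allele2 allele names as called.
#' @param kb a KnowledgeBase.
#' @return numeric score in \[0, 2\].
#' @examples
#' kb <- loadKnowledgeBase()
#' activityScore("DPYD", "*1", "c.557A>G", kb)  # 1.5
#' @export
activityScore <- function(gene, allele1, allele2, kb) {
    rule <- kb@genes$phenotype_rule[kb@genes$gene == gene]
    if (length(rule) == 0L) stop("unknown gene: ", gene)
    if (rule != "activity_score")
        stop(gene, " does not use the activity-score rule")
    al <- kbAlleles(kb, gene)
    refName <- kb@genes$reference_allele[kb@genes$gene == gene]
    one <- function(name) {
        if (name == refName) return(1.0)
        v <- al$activity_value[match(name, al$allele)]
        if (is.na(v)) stop("allele without assigned activity value: ",
            gene, " ", name)
        v
    }
    one(allele1) + one(allele2)
}

.phenotypeOf <- function(gene, allele1, allele2, carrierClass, kb) {
    g <- kb@genes[kb@genes$gene == gene, ]
    refName <- g$reference_allele
    al <- kbAlleles(kb, gene)
    nonRef <- c(allele1, allele2) != refName
    if (carrierClass == "hemizygous") nonRef <- nonRef[1L]
    nVar <- sum(nonRef)
    switch(g$phenotype_rule,
        count_of_nonfunctional = c("normal", "intermediate",
            "poor")[nVar + 1L],
        activity_score = {
            score <- activityScore(gene, allele1, allele2, kb)
            b <- kb@activityBands[kb@activityBands$gene == gene, ]
            if (nrow(b) == 0L) stop("no activity bands for ", gene)
            if (score <= b$poor) "poor"
            else if (score <= b$intermediate) "intermediate"
            else "normal"
        },
        carrier_report = {
            if (nVar == 0L) "normal"
            else if (carrierClass == "hemizygous" &&
                al$function_class[match(allele1, al$allele)] %in%
                    c("decreased", "none")) "deficient"
            else "carrier"
        },
        stop("unknown phenotype rule for ", gene))
}

#' Translate a diplotype call into a metabolizer phenotype
#'
#' Applies the gene's phenotype rule: genes scored by the count of
#' non-functional alleles (UGT1A1, TPMT) map 0/1/2 variant alleles to
#' normal/intermediate/poor; activity-score genes (DPYD, CYP2D6) band
#' the summed score (a CYP2D6 score of 1.0 classifies intermediate);
#' carrier-report genes flag any non-reference allele as carrier, with
#' hemizygous deficiency alleles (male X, G6PD) labelled deficient. For
#' ambiguous calls the phenotype is computed per candidate; if the
#' candidates disagree the call carries every candidate phenotype and a
#' disagreement flag prompting confirmatory testing.
#'
#' @param call one-row data.frame as produced by [callDiplotype()]
#'   (fields sample, gene, allele1, allele2, carrier_class, ambiguous).
#' @param kb a KnowledgeBase.
#' @param candidates optional ranked candidate data.frame for ambiguous
#'   calls.
#' @return one-row data.frame: sample, gene, phenotype, activity_score
#'   (NA unless the activity rule applies), basis (diplotype string),
#'   candidate_phenotypes (";"-joined, NA if unambiguous),
#'   phenotype_disagreement.
#' @export
metabolizerPhenotype <- function(call, kb, candidates = NULL) {
    gene <- call$gene
    ph <- .phenotypeOf(gene, call$allele1, call$allele2,
        call$carrier_class, kb)
    rule <- kb@genes$phenotype_rule[kb@genes$gene == gene]
    score <- if (rule == "activity_score" &&
        call$carrier_class != "hemizygous")
        activityScore(gene, call$allele1, call$allele2, kb)
        else NA_real_
    candPh <- NA_character_
    disagree <- FALSE
    if (isTRUE(call$ambiguous) && !is.null(candidates) &&
        nrow(candidates) > 1L) {
        refName <- kb@genes$reference_allele[kb@genes$gene == gene]
        phs <- vapply(seq_len(nrow(candidates)), function(i) {
            cc <- .carrierClass(candidates$allele1[i],
                candidates$allele2[i], refName, FALSE)
            .phenotypeOf(gene, candidates$allele1[i],
                candidates$allele2[i], cc, kb)
        }, character(1L))
        candPh <- paste(phs, collapse = ";")
        disagree <- length(unique(phs)) > 1L
    }
    data.frame(sample = call$sample, gene = gene, phenotype = ph,
        activity_score = score,
        basis = paste(call$allele1,
            if (call$carrier_class == "hemizygous") "(hemizygous)" else
                call$allele2, sep = "/"),
        candidate_phenotypes = candPh,
        phenotype_disagreement = disagree,
        stringsAsFactors = FALSE)
}

#' Phenotypes for every called gene of a panel result
#'
#' @param panelResult a [SamplePanelResult][SamplePanelResult-class].
#' @param kb a KnowledgeBase.
#' @return data.frame, one row per called gene (see
#'   [metabolizerPhenotype()]).
#' @export
phenotypePanel <- function(panelResult, kb) {
    calls <- panelCalls(panelResult)
    if (nrow(calls) == 0L)
        return(data.frame(sample = character(), gene = character(),
            phenotype = character(), activity_score = numeric(),
            basis = character(), candidate_phenotypes = character(),
            phenotype_disagreement = logical()))
    out <- lapply(seq_len(nrow(calls)), function(i)
        metabolizerPhenotype(calls[i, ], kb,
            candidates = panelCandidates(panelResult)[[calls$gene[i]]]))
    do.call(rbind, c(out, make.row.names = FALSE))
}
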