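## Actionability: join phenotypes with disease and treatment data into
## potential/actual risk findings, toxicity attribution and the
## per-patient report.

.emptyFindings <- function() {
    data.frame(patient = character(), gene = character(),
        drug = character(), disease = character(), tier = character(),
        risk_kind = character(), phenotype = character(),
        stringsAsFactors = FALSE)
}

#' Potential-risk findings for one patient
#'
#' One finding per indication rule matching the patient's primary site,
#' for each gene where the patient carries at least one non-reference
#' allele -- potential risk is independent of treatment actually
#' received. Wild-type patients yield no findings; a disease with no
#' CPIC level-A drug in its NCCN regimens yields an empty list with a
#' warning.
#'
#' @param patient one-row data.frame with at least `patient` and
#'   `primary_site`.
#' @param calls panel calls data.frame (fields gene, carrier_class) for
#'   the patient, as from [panelCalls()].
#' @param kb a KnowledgeBase.
#' @param phenotypes optional phenotype data.frame from
#'   [phenotypePanel()]; phenotype labels are joined into the findings.
#' @return data.frame of RiskFindings (risk_kind "potential").
#' @export
potentialRisk <- function(patient, calls, kb, phenotypes = NULL) {
    rules <- indicationRulesFor(kb, patient$primary_site)
    if (nrow(rules) == 0L) {
        warning("no indication rules for disease '",
            patient$primary_site, "'")
        return(.emptyFindings())
    }
    carrier <- calls$gene[!calls$carrier_class %in% "wild_type"]
    hit <- rules[rules$gene %in% carrier, , drop = FALSE]
    if (nrow(hit) == 0L) return(.emptyFindings())
    ph <- if (is.null(phenotypes)) rep(NA_character_, nrow(hit)) else
        phenotypes$phenotype[match(hit$gene, phenotypes$gene)]
    data.frame(patient = patient$patient, gene = hit$gene,
        drug = hit$drug, disease = hit$disease, tier = hit$tier,
        risk_kind = "potential", phenotype = ph,
        stringsAsFactors = FALSE)
}

#' Actual-risk findings: potential findings realized by treatment
#'
#' Filters potential findings down to those whose drug appears in a
#' treatment record delivered at the institution (`received_here`).
#' Patients treated elsewhere are excluded here and counted separately
#' in the risk matrix denominators.
#'
#' @param findings potential findings from [potentialRisk()].
#' @param treatments data.frame: patient, drug, received_here.
#' @return the subset of `findings`, re-tagged risk_kind "actual".
#' @export
actualRisk <- function(findings, treatments) {
    if (nrow(findings) == 0L) return(.emptyFindings())
    here <- treatments[treatments$received_here %in% TRUE, ,
        drop = FALSE]
    keep <- paste(findings$patient, findings$drug) %in%
        paste(here$patient, here$drug)
    out <- findings[keep, , drop = FALSE]
    if (nrow(out) > 0L) out$risk_kind <- "actual"
    rownames(out) <- NULL
    out
}

#' Attribute a treatment's toxicity to genotype
#'
#' A treatment course is genotype-related toxic when at least one
#' adverse event belongs to the drug--gene pair's genotype-associated
#' event list, at least one clinical action (dose reduction, delay,
#' discontinuation, hospitalization, death) occurred, and the reason
#' that triggered the action is not an excluded cause (allergic
#' reaction, fatigue, patient request). Events on the excluded list
#' never qualify regardless of action.
#'
#' @param treatment one-row data.frame: patient, drug, adverse_events
#'   and actions (";"-separated), action_reason (the event that
#'   triggered the recorded actions; may be NA).
#' @param pair one-row data.frame from [kbDrugGenePairs()] with matching
#'   drug.
#' @return one-row data.frame: patient, drug, genotype_related,
#'   qualifying_events, qualifying_actions.
#' @export
attributeToxicity <- function(treatment, pair) {
    stopifnot(treatment$drug == pair$drug)
    events <- splitEvents(treatment$adverse_events)
    actions <- splitEvents(treatment$actions)
    qualify <- setdiff(intersect(events, splitEvents(pair$events)),
        splitEvents(pair$excluded))
    reason <- treatment$action_reason
    reasonOk <- if (is.na(reason) || !nzchar(reason))
        length(qualify) > 0L
        else reason %in% qualify
    related <- length(qualify) > 0L && length(actions) > 0L && reasonOk
    data.frame(patient = treatment$patient, drug = treatment$drug,
        genotype_related = related,
        qualifying_events = paste(qualify, collapse = ";"),
        qualifying_actions = if (related)
            paste(actions, collapse = ";") else "",
        stringsAsFactors = FALSE)
}

#' Toxicity attribution for every treated unit of a cohort
#'
#' Applies [attributeToxicity()] to each (patient, drug) treatment row
#' delivered at the institution whose drug has a toxicity-associated
#' anti-cancer drug--gene pair. Efficacy pairs (tamoxifen--CYP2D6) are
#' excluded: they produce risk findings but no toxicity comparison.
#'
#' @param treatments treatment data.frame (see [attributeToxicity()]
#'   plus received_here).
#' @param kb a KnowledgeBase.
#' @return data.frame of ToxicityCalls, one row per treated unit.
#' @export
attributeCohortToxicity <- function(treatments, kb) {
    pairs <- kbDrugGenePairs(kb)
    pairs <- pairs[pairs$anti_cancer & pairs$association == "toxicity", ,
        drop = FALSE]
    tr <- treatments[treatments$received_here %in% TRUE &
        treatments$drug %in% pairs$drug, , drop = FALSE]
    if (nrow(tr) == 0L)
        return(data.frame(patient = character(), drug = character(),
            gene = character(), genotype_related = logical(),
            qualifying_events = character(),
            qualifying_actions = character(), stringsAsFactors = FALSE))
    out <- lapply(seq_len(nrow(tr)), function(i) {
        p <- pairs[match(tr$drug[i], pairs$drug), ]
        cbind(attributeToxicity(tr[i, ], p),
            data.frame(gene = p$gene, stringsAsFactors = FALSE))
    })
    res <- do.call(rbind, c(out, make.row.names = FALSE))
    res[, c("patient", "drug", "gene", "genotype_related",
        "qualifying_events", "qualifying_actions")]
}

#' Render the per-patient screening report
#'
#' Deterministic plain-text report listing, per gene: diplotype,
#' zygosity, phenotype, disease-relevant drugs with their NCCN tier, and
#' ambiguity caveats recommending confirmatory testing.
#'
#' @param patient one-row data.frame (patient, primary_site, ...).
#' @param panelResult a [SamplePanelResult][SamplePanelResult-class].
#' @param phenotypes data.frame from [phenotypePanel()].
#' @param findings data.frame from [potentialRisk()].
#' @param kb a KnowledgeBase.
#' @return character vector of report lines.
#' @export
renderPatientReport <- function(patient, panelResult, phenotypes,
        findings, kb) {
    calls <- panelCalls(panelResult)
    lines <- c(
        sprintf("Pharmacogenomic screening report -- %s",
            patient$patient),
        sprintf("Primary cancer site: %s", patient$primary_site),
        sprintf("Knowledge base: %s", kbVersion(kb)),
        "",
        "Gene panel results:")
    for (i in seq_len(nrow(calls))) {
        cl <- calls[i, ]
        ph <- phenotypes[phenotypes$gene == cl$gene, ]
        lines <- c(lines, sprintf("  %-8s %-22s %-22s %s", cl$gene,
            paste(cl$allele1, cl$allele2, sep = "/"),
            cl$carrier_class, ph$phenotype[1L]))
        if (isTRUE(cl$ambiguous)) {
            cand <- panelCandidates(panelResult)[[cl$gene]]
            lines <- c(lines, sprintf(
                "           ambiguous call; candidates: %s -- %s",
                paste(sprintf("%s/%s (%.3f)", cand$allele1,
                    cand$allele2, cand$weight), collapse = ", "),
                "confirmatory genotyping recommended"))
        }
    }
    unc <- panelUncallable(panelResult)
    if (nrow(unc) > 0L)
        lines <- c(lines, "", "Not callable:",
            sprintf("  %-8s %s", unc$gene, unc$reason))
    act <- findings
    if (nrow(act) > 0L) {
        lines <- c(lines, "", "Disease-relevant drug considerations:")
        for (i in seq_len(nrow(act)))
            lines <- c(lines, sprintf(
                "  %s (%s tier): %s variant carrier%s", act$drug[i],
                act$tier[i], act$gene[i],
                if (!is.na(act$phenotype[i]))
                    sprintf(", phenotype %s", act$phenotype[i]) else ""))
    } else {
        lines <- c(lines, "",
            "No disease-relevant actionable variants identified.")
    }
    lines
}
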