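#' @import methods
NULL

#' KnowledgeBase: the pharmacogene panel definition
#'
#' Holds the screened panel as data: gene definitions, star-allele /
#' variant-haplotype definitions with their defining genomic variants
#' (GRCh37, 1-based, VCF anchored-base convention), CPIC function classes
#' and activity values, expected population allele frequencies, the CPIC
#' level-A drug--gene pairs, and the NCCN-derived
#' disease -> drug -> gene indication matrix with preferred/other tiers.
#'
#' All slots are plain data.frames so the object can be serialized to and
#' reloaded from the YAML configuration without loss
#' (see [loadKnowledgeBase()], [writeKnowledgeBase()]).
#'
#' @slot genes data.frame: gene, chromosome_mode (autosomal/x_linked),
#'   reference_allele, phenotype_rule (count_of_nonfunctional /
#'   activity_score / carrier_report), tested_note.
#' @slot alleles data.frame: gene, allele, function_class
#'   (normal/decreased/none/unassigned), activity_value (NA unless the
#'   gene uses the activity-score rule), expected_frequency,
#'   frequency_source (CPIC/gnomAD/ExAC).
#' @slot variants data.frame: gene, allele, chrom, pos, ref, alt, rsid;
#'   one row per defining variant (multi-row alleles are multi-variant
#'   haplotypes such as TPMT *3A).
#' @slot activityBands data.frame: gene, poor, intermediate, normal
#'   (upper bounds of the activity-score bands).
#' @slot indistinguishableGroups data.frame: gene, label, member.
#' @slot drugGenePairs data.frame: drug, gene, association
#'   (toxicity/efficacy), anti_cancer, events, excluded (";"-separated
#'   event vocabularies).
#' @slot indicationRules data.frame: disease, drug, gene, tier.
#' @slot synonyms list with character maps `drugs` and `diseases`.
#' @slot version character scalar.
#' @slot cache environment holding derived per-gene dosage lookup tables
#'   (not part of object identity).
#'
#' @seealso [loadKnowledgeBase()], [validateKnowledgeBase()],
#'   [alleleForVariant()], [indicationRulesFor()]
#' @export
setClass("KnowledgeBase",
    representation(
        genes = "data.frame",
        alleles = "data.frame",
        variants = "data.frame",
        activityBands = "data.frame",
        indistinguishableGroups = "data.frame",
        drugGenePairs = "data.frame",
        indicationRules = "data.frame",
        synonyms = "list",
        version = "character",
        cache = "environment"
    )
)

setValidity("KnowledgeBase", function(object) {
    v <- validateKnowledgeBase(object)
    if (length(v) == 0L) TRUE else v
})

#' @describeIn KnowledgeBase-class compact summary
#' @param object a KnowledgeBase
#' @export
setMethod("show", "KnowledgeBase", function(object) {
    cat("KnowledgeBase (", object@version, ")\n", sep = "")
    cat("  genes:           ", nrow(object@genes), "\n")
    cat("  alleles:         ", nrow(object@alleles), "\n")
    cat("  drug-gene pairs: ", nrow(object@drugGenePairs),
        " (", sum(object@drugGenePairs$anti_cancer), " anti-cancer)\n",
        sep = "")
    cat("  indication rules:", nrow(object@indicationRules), "\n")
    invisible(NULL)
})

#' SyntheticCohort: generated patients with ground truth
#'
#' Container produced by [generateCohort()]. Ground-truth planted
#' diplotypes live in `truth`; `observations` are the variant dosages the
#' emitted VCF encodes; `treatments` carry simulated drug exposure,
#' adverse events and resulting clinical actions.
#'
#' @slot patients data.frame: patient, primary_site, stage, gender,
#'   race_ethnicity, age_at_diagnosis.
#' @slot truth data.frame: patient, gene, allele1, allele2,
#'   carrier_class, phased (TRUE plants carry known cis/trans phase even
#'   where the unphased VCF cannot distinguish it).
#' @slot observations data.frame: patient, chrom, pos, ref, alt, dosage,
#'   hemizygous.
#' @slot treatments data.frame: patient, drug, received_here,
#'   adverse_events, actions, action_reason.
#' @slot config list: the [SyntheticConfig][defaultCalibration()] the
#'   cohort was generated from (including seed).
#' @export
setClass("SyntheticCohort",
    representation(
        patients = "data.frame",
        truth = "data.frame",
        observations = "data.frame",
        treatments = "data.frame",
        config = "list"
    )
)

setValidity("SyntheticCohort", function(object) {
    msg <- character()
    np <- nrow(object@patients)
    if (np > 0L && nrow(object@truth) == 0L)
        msg <- c(msg, "truth table is empty for a non-empty cohort")
    if (nrow(object@truth) > 0L &&
        !all(object@truth$patient %in% object@patients$patient))
        msg <- c(msg, "truth references unknown patients")
    if (nrow(object@treatments) > 0L &&
        !all(object@treatments$patient %in% object@patients$patient))
        msg <- c(msg, "treatments reference unknown patients")
    if (length(msg) == 0L) TRUE else msg
})

#' @describeIn SyntheticCohort-class compact summary
#' @param object a SyntheticCohort
#' @export
setMethod("show", "SyntheticCohort", function(object) {
    cat("SyntheticCohort:", nrow(object@patients), "patients,",
        nrow(object@treatments), "treatment records",
        "(seed", object@config$seed, ")\n")
    invisible(NULL)
})

#' @rdname SyntheticCohort-class
#' @param x a SyntheticCohort
#' @export
cohortPatients <- function(x) x@patients

#' @rdname SyntheticCohort-class
#' @export
cohortTruth <- function(x) x@truth

#' @rdname SyntheticCohort-class
#' @export
cohortObservations <- function(x) x@observations

#' @rdname SyntheticCohort-class
#' @export
cohortTreatments <- function(x) x@treatments

#' @rdname SyntheticCohort-class
#' @export
cohortConfig <- function(x) x@config
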