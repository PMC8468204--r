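## Knowledge-base loading, validation and lookups.

.FUNCTION_CLASSES <- c("normal", "decreased", "none", "unassigned")
.PHENOTYPE_RULES <- c("count_of_nonfunctional", "activity_score",
    "carrier_report")
.CHROMOSOME_MODES <- c("autosomal", "x_linked")
.TIERS <- c("preferred", "other")

## the six anti-cancer CPIC level-A pairs the KB must always carry
.MANDATORY_PAIRS <- data.frame(
    drug = c("irinotecan", "fluorouracil", "capecitabine",
        "mercaptopurine", "thioguanine", "tamoxifen"),
    gene = c("UGT1A1", "DPYD", "DPYD", "TPMT", "TPMT", "CYP2D6"),
    stringsAsFactors = FALSE)

.variantId <- function(chrom, pos, ref, alt) {
    paste(chrom, pos, ref, alt, sep = ":")
}

#' Load a knowledge base from its YAML configuration
#'
#' Parses the structured-text knowledge-base file (see the bundled
#' default under `extdata/kb/default_kb.yaml` for the schema) and
#' validates every record. The bundled default encodes the 15-gene CPIC
#' level-A panel: allele definitions with expected population
#' frequencies, the six anti-cancer drug--gene pairs, and the full
#' NCCN-derived disease/drug/gene indication matrix.
#'
#' @param path path to a KB YAML file; defaults to the bundled KB.
#' @return a validated [KnowledgeBase][KnowledgeBase-class].
#' @examples
#' kb <- loadKnowledgeBase()
#' kb
#' @export
loadKnowledgeBase <- function(path = defaultKnowledgeBasePath()) {
    if (!file.exists(path))
        stop("knowledge base file not found: ", path)
    raw <- yaml::read_yaml(path)
    if (is.null(raw$genes) || length(raw$genes) == 0L)
        stop("knowledge base defines no genes: ", path)

    genes <- do.call(rbind, lapply(raw$genes, function(g) {
        data.frame(gene = g$gene,
            chromosome_mode = g$chromosome_mode %||% "autosomal",
            reference_allele = g$reference_allele %||% "*1",
            phenotype_rule = g$phenotype_rule %||% "carrier_report",
            tested_note = g$tested_note %||% NA_character_,
            stringsAsFactors = FALSE)
    }))

    alleles <- do.call(rbind, lapply(raw$genes, function(g) {
        if (length(g$alleles) == 0L) return(NULL)
        do.call(rbind, lapply(g$alleles, function(a) {
            data.frame(gene = g$gene, allele = a$name,
                function_class = a$function_class %||% "unassigned",
                activity_value = as.numeric(a$activity_value %||% NA),
                expected_frequency = as.numeric(a$expected_frequency %||% NA),
                frequency_source = a$frequency_source %||% NA_character_,
                stringsAsFactors = FALSE)
        }))
    }))

    variants <- do.call(rbind, lapply(raw$genes, function(g) {
        if (length(g$alleles) == 0L) return(NULL)
        do.call(rbind, lapply(g$alleles, function(a) {
            do.call(rbind, lapply(a$defining_variants, function(v) {
                data.frame(gene = g$gene, allele = a$name,
                    chrom = as.character(v$chrom), pos = as.integer(v$pos),
                    ref = v$ref, alt = v$alt,
                    rsid = v$rsid %||% NA_character_,
                    stringsAsFactors = FALSE)
            }))
        }))
    }))

    bands <- do.call(rbind, lapply(raw$genes, function(g) {
        if (is.null(g$activity_bands)) return(NULL)
        data.frame(gene = g$gene,
            poor = as.numeric(g$activity_bands$poor),
            intermediate = as.numeric(g$activity_bands$intermediate),
            normal = as.numeric(g$activity_bands$normal),
            stringsAsFactors = FALSE)
    }))
    if (is.null(bands))
        bands <- data.frame(gene = character(), poor = numeric(),
            intermediate = numeric(), normal = numeric())

    groups <- do.call(rbind, lapply(raw$genes, function(g) {
        if (is.null(g$indistinguishable_groups)) return(NULL)
        do.call(rbind, lapply(g$indistinguishable_groups, function(grp) {
            data.frame(gene = g$gene, label = grp$label,
                member = unlist(grp$members), stringsAsFactors = FALSE)
        }))
    }))
    if (is.null(groups))
        groups <- data.frame(gene = character(), label = character(),
            member = character())

    pairs <- do.call(rbind, lapply(raw$drug_gene_pairs, function(p) {
        data.frame(drug = p$drug, gene = p$gene,
            association = p$association,
            anti_cancer = isTRUE(p$anti_cancer),
            events = paste(unlist(p$genotype_related_adverse_events),
                collapse = ";"),
            excluded = paste(unlist(p$excluded_events), collapse = ";"),
            stringsAsFactors = FALSE)
    }))

    rules <- do.call(rbind, lapply(raw$indication_rules, function(r) {
        data.frame(disease = r$disease, drug = r$drug, gene = r$gene,
            tier = r$tier, stringsAsFactors = FALSE)
    }))

    synonyms <- list(
        drugs = unlist(raw$synonyms$drugs %||% list()),
        diseases = unlist(raw$synonyms$diseases %||% list()))

    kb <- new("KnowledgeBase", genes = genes, alleles = alleles,
        variants = variants, activityBands = bands,
        indistinguishableGroups = groups, drugGenePairs = pairs,
        indicationRules = rules, synonyms = synonyms,
        version = as.character(raw$version %||% "unversioned"),
        cache = new.env(parent = emptyenv()))
    kb
}

#' @rdname loadKnowledgeBase
#' @export
defaultKnowledgeBasePath <- function() {
    system.file("extdata", "kb", "default_kb.yaml", package = "pgxscreen",
        mustWork = TRUE)
}

#' Serialize a knowledge base back to YAML
#'
#' Inverse of [loadKnowledgeBase()]: the written file re-parses to an
#' equal KnowledgeBase (round-trip property).
#'
#' @param kb a KnowledgeBase.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeKnowledgeBase <- function(kb, path) {
    geneList <- lapply(seq_len(nrow(kb@genes)), function(i) {
        g <- kb@genes[i, ]
        al <- kb@alleles[kb@alleles$gene == g$gene, , drop = FALSE]
        entry <- list(gene = g$gene,
            chromosome_mode = g$chromosome_mode,
            reference_allele = g$reference_allele,
            phenotype_rule = g$phenotype_rule)
        if (!is.na(g$tested_note)) entry$tested_note <- g$tested_note
        bi <- kb@activityBands[kb@activityBands$gene == g$gene, ,
            drop = FALSE]
        if (nrow(bi) == 1L)
            entry$activity_bands <- list(poor = bi$poor,
                intermediate = bi$intermediate, normal = bi$normal)
        gr <- kb@indistinguishableGroups[
            kb@indistinguishableGroups$gene == g$gene, , drop = FALSE]
        if (nrow(gr) > 0L)
            entry$indistinguishable_groups <- lapply(
                split(gr, gr$label), function(x)
                    list(label = x$label[1L], members = as.list(x$member)))
        entry$alleles <- lapply(seq_len(nrow(al)), function(j) {
            a <- al[j, ]
            vr <- kb@variants[kb@variants$gene == a$gene &
                kb@variants$allele == a$allele, , drop = FALSE]
            out <- list(name = a$allele, function_class = a$function_class)
            if (!is.na(a$activity_value))
                out$activity_value <- a$activity_value
            out$expected_frequency <- a$expected_frequency
            out$frequency_source <- a$frequency_source
            out$defining_variants <- lapply(seq_len(nrow(vr)), function(k)
                list(chrom = vr$chrom[k], pos = vr$pos[k],
                    ref = vr$ref[k], alt = vr$alt[k],
                    rsid = if (is.na(vr$rsid[k])) NULL else vr$rsid[k]))
            out
        })
        entry
    })
    pairList <- lapply(seq_len(nrow(kb@drugGenePairs)), function(i) {
        p <- kb@drugGenePairs[i, ]
        list(drug = p$drug, gene = p$gene, association = p$association,
            anti_cancer = p$anti_cancer,
            genotype_related_adverse_events =
                as.list(splitEvents(p$events)),
            excluded_events = as.list(splitEvents(p$excluded)))
    })
    ruleList <- lapply(seq_len(nrow(kb@indicationRules)), function(i) {
        r <- kb@indicationRules[i, ]
        list(disease = r$disease, drug = r$drug, gene = r$gene,
            tier = r$tier)
    })
    doc <- list(version = kb@version, genome_build = "GRCh37",
        genes = geneList, drug_gene_pairs = pairList,
        indication_rules = ruleList,
        synonyms = list(drugs = as.list(kb@synonyms$drugs),
            diseases = as.list(kb@synonyms$diseases)))
    yaml::write_yaml(doc, path)
    invisible(path)
}

splitEvents <- function(x) {
    if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";",
        fixed = TRUE)[[1L]]
}

#' Validate a knowledge base
#'
#' Checks every structural invariant of the panel definition. Violations
#' are returned as data (a character vector naming type, record and
#' rule), never thrown, so a KB under construction can be inspected.
#'
#' @param kb a KnowledgeBase.
#' @return character vector of violation descriptions; empty when valid.
#' @export
validateKnowledgeBase <- function(kb) {
    v <- character()
    g <- kb@genes; a <- kb@alleles; vr <- kb@variants

    bad <- !g$phenotype_rule %in% .PHENOTYPE_RULES
    if (any(bad)) v <- c(v, paste0("GeneDefinition ", g$gene[bad],
        ": unknown phenotype_rule '", g$phenotype_rule[bad], "'"))
    bad <- !g$chromosome_mode %in% .CHROMOSOME_MODES
    if (any(bad)) v <- c(v, paste0("GeneDefinition ", g$gene[bad],
        ": unknown chromosome_mode '", g$chromosome_mode[bad], "'"))
    if (anyDuplicated(g$gene))
        v <- c(v, paste0("GeneDefinition: duplicated gene symbol '",
            unique(g$gene[duplicated(g$gene)]), "'"))

    if (nrow(a) > 0L) {
        dup <- duplicated(paste(a$gene, a$allele))
        if (any(dup)) v <- c(v, paste0("AlleleDefinition ", a$gene[dup],
            " ", a$allele[dup], ": duplicated allele name within gene"))
        bad <- !a$function_class %in% .FUNCTION_CLASSES
        if (any(bad)) v <- c(v, paste0("AlleleDefinition ", a$gene[bad],
            " ", a$allele[bad], ": unknown function_class '",
            a$function_class[bad], "'"))
        bad <- is.na(a$expected_frequency) | a$expected_frequency < 0 |
            a$expected_frequency > 1
        if (any(bad)) v <- c(v, paste0("AlleleDefinition ", a$gene[bad],
            " ", a$allele[bad],
            ": expected_frequency outside [0,1]"))
        ok <- !is.na(a$frequency_source) &
            a$frequency_source %in% c("CPIC", "gnomAD", "ExAC")
        if (any(!ok)) v <- c(v, paste0("AlleleDefinition ", a$gene[!ok],
            " ", a$allele[!ok], ": frequency_source must be one of ",
            "CPIC/gnomAD/ExAC"))
        ## activity_value present iff the gene uses the activity rule
        rule <- g$phenotype_rule[match(a$gene, g$gene)]
        bad <- (rule == "activity_score") != !is.na(a$activity_value)
        if (any(bad)) v <- c(v, paste0("AlleleDefinition ", a$gene[bad],
            " ", a$allele[bad], ": activity_value must be present iff ",
            "the gene uses the activity_score rule"))
        bad <- !is.na(a$activity_value) &
            !a$activity_value %in% c(0, 0.5, 1)
        if (any(bad)) v <- c(v, paste0("AlleleDefinition ", a$gene[bad],
            " ", a$allele[bad], ": activity_value not in {0, 0.5, 1}"))
        ## every allele needs >= 1 defining variant
        key <- paste(a$gene, a$allele)
        hasVar <- key %in% paste(vr$gene, vr$allele)
        if (any(!hasVar)) v <- c(v, paste0("AlleleDefinition ",
            a$gene[!hasVar], " ", a$allele[!hasVar],
            ": no defining variants"))
    }

    if (nrow(vr) > 0L) {
        bad <- vr$pos < 1L
        if (any(bad)) v <- c(v, paste0("VariantKey ", vr$gene[bad], " ",
            vr$allele[bad], ": position < 1"))
        bad <- vr$ref == vr$alt
        if (any(bad)) v <- c(v, paste0("VariantKey ", vr$gene[bad], " ",
            vr$allele[bad], ": ref equals alt"))
        ## a VariantKey is unique across genes (within-gene sharing is
        ## what creates haplotype ambiguity and is allowed)
        id <- .variantId(vr$chrom, vr$pos, vr$ref, vr$alt)
        byGene <- unique(data.frame(id = id, gene = vr$gene))
        dup <- byGene$id[duplicated(byGene$id)]
        if (length(dup) > 0L) v <- c(v, paste0("VariantKey ", dup,
            ": shared across more than one gene"))
    }

    p <- kb@drugGenePairs
    if (nrow(p) > 0L) {
        bad <- !p$association %in% c("toxicity", "efficacy")
        if (any(bad)) v <- c(v, paste0("DrugGenePair ", p$drug[bad], "-",
            p$gene[bad], ": unknown association"))
        bad <- p$association == "toxicity" & !nzchar(p$events)
        if (any(bad)) v <- c(v, paste0("DrugGenePair ", p$drug[bad], "-",
            p$gene[bad],
            ": toxicity pair with no genotype-related adverse events"))
    }
    have <- paste(p$drug, p$gene)
    need <- paste(.MANDATORY_PAIRS$drug, .MANDATORY_PAIRS$gene)
    miss <- !need %in% have
    if (any(miss)) v <- c(v, paste0("DrugGenePair: mandatory ",
        "anti-cancer pair missing: ", need[miss]))

    r <- kb@indicationRules
    if (nrow(r) > 0L) {
        bad <- !r$tier %in% .TIERS
        if (any(bad)) v <- c(v, paste0("IndicationRule ", r$disease[bad],
            "/", r$drug[bad], ": unknown tier '", r$tier[bad], "'"))
        dup <- duplicated(paste(r$disease, r$drug))
        if (any(dup)) v <- c(v, paste0("IndicationRule ", r$disease[dup],
            "/", r$drug[dup], ": (disease, drug) appears more than once"))
        bad <- !r$gene %in% g$gene
        if (any(bad)) v <- c(v, paste0("IndicationRule ", r$disease[bad],
            "/", r$drug[bad], ": gene '", r$gene[bad],
            "' has no GeneDefinition"))
        bad <- !paste(r$drug, r$gene) %in% have
        if (any(bad)) v <- c(v, paste0("IndicationRule ", r$disease[bad],
            "/", r$drug[bad], ": no matching DrugGenePair"))
    }
    v
}

#' Look up the allele defined by a genomic variant
#'
#' Returns the allele of `gene` whose defining variants contain the key.
#' When a variant is shared between a multi-variant haplotype and its
#' single-variant components (e.g. TPMT *3A vs *3B/*3C), the most
#' specific allele (smallest defining set) containing the key is
#' returned. Variants inside an indistinguishable group resolve to the
#' group's combined label.
#'
#' @param kb a KnowledgeBase.
#' @param gene gene symbol present in `kb`.
#' @param chrom,pos,ref,alt the variant key (GRCh37, 1-based, VCF
#'   anchored-base spelling).
#' @return one-row data.frame from the allele table, or `NULL` when no
#'   allele of the gene is defined by the variant.
#' @export
alleleForVariant <- function(kb, gene, chrom, pos, ref, alt) {
    if (!gene %in% kb@genes$gene)
        stop("unknown gene: ", gene)
    vr <- kb@variants[kb@variants$gene == gene, , drop = FALSE]
    hit <- vr$chrom == as.character(chrom) & vr$pos == as.integer(pos) &
        vr$ref == ref & vr$alt == alt
    if (!any(hit)) return(NULL)
    cand <- unique(vr$allele[hit])
    if (length(cand) > 1L) {
        sizes <- vapply(cand, function(al)
            sum(vr$allele == al), integer(1L))
        cand <- cand[order(sizes, cand)][1L]
    }
    kb@alleles[kb@alleles$gene == gene & kb@alleles$allele == cand, ,
        drop = FALSE]
}

#' Indication rules applying to one disease
#'
#' All disease/drug/gene rows of the indication matrix matching the given
#' primary-site label (after synonym mapping), preferred tier first.
#' Diseases without any CPIC level-A drug in their NCCN regimens yield an
#' empty set.
#'
#' @param kb a KnowledgeBase.
#' @param disease primary-site label.
#' @return data.frame of matching rules (possibly zero rows).
#' @export
indicationRulesFor <- function(kb, disease) {
    disease <- canonicalDisease(kb, disease)
    r <- kb@indicationRules[kb@indicationRules$disease == disease, ,
        drop = FALSE]
    r[order(match(r$tier, .TIERS), r$drug), , drop = FALSE]
}

#' @rdname indicationRulesFor
#' @param label free-text disease or drug label
#' @export
canonicalDisease <- function(kb, label) {
    m <- kb@synonyms$diseases
    ifelse(label %in% names(m), unname(m[label]), label)
}

#' @rdname indicationRulesFor
#' @export
canonicalDrug <- function(kb, label) {
    m <- kb@synonyms$drugs
    ifelse(label %in% names(m), unname(m[label]), label)
}

## gene accessors -----------------------------------------------------

#' Accessors for KnowledgeBase tables
#'
#' @param kb a KnowledgeBase.
#' @param gene optional gene symbol filter.
#' @return the requested table as a data.frame.
#' @name kb-accessors
NULL

#' @rdname kb-accessors
#' @export
kbGenes <- function(kb) kb@genes

#' @rdname kb-accessors
#' @export
kbAlleles <- function(kb, gene = NULL) {
    if (is.null(gene)) return(kb@alleles)
    kb@alleles[kb@alleles$gene == gene, , drop = FALSE]
}

#' @rdname kb-accessors
#' @export
kbVariants <- function(kb, gene = NULL) {
    if (is.null(gene)) return(kb@variants)
    kb@variants[kb@variants$gene == gene, , drop = FALSE]
}

#' @rdname kb-accessors
#' @export
kbDrugGenePairs <- function(kb) kb@drugGenePairs

#' @rdname kb-accessors
#' @export
kbIndicationRules <- function(kb) kb@indicationRules

#' @rdname kb-accessors
#' @export
kbVersion <- function(kb) kb@version

`%||%` <- function(a, b) if (is.null(a)) b else a
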