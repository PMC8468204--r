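## Synthetic-cohort generation: cohorts with the statistical structure
## the analysis assumes (study disease mix, per-gene genotype
## frequencies, indication-consistent treatment exposure, genotype-
## dependent toxicity), plus ground truth, VCFs and clinical tables.

#' Default generator calibration
#'
#' Loads the study calibration shipped with the package: the refined
#' disease mix (registry sites at indication-matrix granularity),
#' per-(gene, allele) patient-level genotype counts, demographic mixes,
#' treatment-exposure probabilities by indication tier, and the
#' genotype-dependent toxicity rates (7/9 for non-normal metabolizers,
#' 13/36 for normal ones).
#'
#' @param path calibration YAML (defaults to the bundled file).
#' @param nPatients cohort size override (default: calibrated size).
#' @param seed RNG seed stored in the config.
#' @return a SyntheticConfig list: n_patients, seed, disease_mix
#'   (probabilities), demographics, genotype_model (data.frame gene,
#'   allele, p_hom, p_het), treatment_model, toxicity_model.
#' @examples
#' cfg <- defaultCalibration()
#' cfg$disease_mix[["Colon/rectal"]]  # 55/291
#' @export
defaultCalibration <- function(path = system.file("extdata", "kb",
        "study_calibration.yaml", package = "pgxscreen",
        mustWork = TRUE), nPatients = NULL, seed = 1L) {
    raw <- yaml::read_yaml(path)
    nCal <- raw$n_patients
    mix <- unlist(raw$disease_mix) / nCal
    gm <- do.call(rbind, lapply(names(raw$genotype_model), function(g) {
        entry <- raw$genotype_model[[g]]
        do.call(rbind, lapply(names(entry), function(al)
            data.frame(gene = g, allele = al,
                p_hom = entry[[al]]$hom / nCal,
                p_het = entry[[al]]$het / nCal,
                stringsAsFactors = FALSE)))
    }))
    dem <- raw$demographics
    list(n_patients = if (is.null(nPatients)) nCal else
            as.integer(nPatients),
        seed = as.integer(seed),
        disease_mix = mix,
        demographics = list(
            gender = unlist(dem$gender) / sum(unlist(dem$gender)),
            race_ethnicity = unlist(dem$race_ethnicity) /
                sum(unlist(dem$race_ethnicity)),
            stage = unlist(dem$stage) / sum(unlist(dem$stage)),
            age = dem$age),
        genotype_model = gm,
        treatment_model = raw$treatment_model,
        toxicity_model = raw$toxicity_model,
        printed_gene_totals = raw$printed_gene_totals)
}

#' Validate a synthetic-cohort configuration
#'
#' @param config a SyntheticConfig list.
#' @return character vector of violations; empty when valid.
#' @export
validateSyntheticConfig <- function(config) {
    v <- character()
    if (is.null(config$n_patients) || config$n_patients < 1)
        v <- c(v, "n_patients must be >= 1")
    mix <- config$disease_mix
    if (any(mix < 0 | mix > 1))
        v <- c(v, "disease_mix probabilities outside [0,1]")
    if (abs(sum(mix) - 1) > 1e-9)
        v <- c(v, sprintf("disease_mix sums to %.12f, not 1", sum(mix)))
    gm <- config$genotype_model
    bad <- gm$p_hom < 0 | gm$p_het < 0 | gm$p_hom + gm$p_het > 1
    if (any(bad))
        v <- c(v, paste0("genotype_model ", gm$gene[bad], " ",
            gm$allele[bad], ": hom/het probabilities invalid"))
    tm <- config$toxicity_model
    for (f in c("variant_rate", "normal_rate", "nuisance_event_rate"))
        if (is.null(tm[[f]]) || tm[[f]] < 0 || tm[[f]] > 1)
            v <- c(v, paste0("toxicity_model$", f, " outside [0,1]"))
    v
}

.GENOTOX_ACTIONS <- c("dose_reduction", "delay", "discontinuation",
    "hospitalization")
.NUISANCE_EVENTS <- c("fatigue", "allergic_reaction")

## vectorized per-gene genotype draw with <= 2 variant copies enforced
## by rejection; returns an n x k copies matrix
.drawGeneCopies <- function(n, pHom, pHet, maxIter = 100L) {
    k <- length(pHom)
    draw <- function(rows) {
        C <- matrix(0L, length(rows), k)
        for (j in seq_len(k)) {
            u <- stats::runif(length(rows))
            C[, j] <- ifelse(u < pHom[j], 2L,
                ifelse(u < pHom[j] + pHet[j], 1L, 0L))
        }
        C
    }
    C <- draw(seq_len(n))
    it <- 0L
    repeat {
        bad <- which(rowSums(C) > 2L)
        if (length(bad) == 0L || it >= maxIter) break
        C[bad, ] <- draw(bad)
        it <- it + 1L
    }
    C[rowSums(C) > 2L, ] <- 0L  # unreachable in practice
    C
}

#' Generate a synthetic cohort
#'
#' Reproducible given the config seed. Diseases are sampled from the
#' disease mix; per gene an independent categorical draw per allele
#' plants wild-type/heterozygous/homozygous genotypes with at most two
#' variant allele copies per gene enforced by rejection (TPMT cis
#' (*3A) and trans (*3B + *3C) plants both arise, so unphased-ambiguity
#' cases exist with known truth); X-linked genes respect gender
#' (non-female carriers are hemizygous); treatments are drawn only for
#' diseases with a matching indication rule, with genotype-related and
#' nuisance adverse events per the toxicity model and clinical actions
#' attached to genotype-related events.
#'
#' @param config a SyntheticConfig from [defaultCalibration()].
#' @param kb a KnowledgeBase.
#' @return a [SyntheticCohort][SyntheticCohort-class].
#' @export
generateCohort <- function(config = defaultCalibration(),
        kb = loadKnowledgeBase()) {
    viol <- validateSyntheticConfig(config)
    if (length(viol) > 0L)
        stop("invalid synthetic config:\n  ",
            paste(viol, collapse = "\n  "))
    set.seed(config$seed)
    n <- as.integer(config$n_patients)
    ids <- sprintf("P%06d", seq_len(n))
    dem <- config$demographics
    ageSd <- (dem$age$iqr_high - dem$age$iqr_low) / 1.349
    patients <- data.frame(patient = ids,
        primary_site = sample(names(config$disease_mix), n,
            replace = TRUE, prob = config$disease_mix),
        stage = sample(names(dem$stage), n, replace = TRUE,
            prob = dem$stage),
        gender = sample(names(dem$gender), n, replace = TRUE,
            prob = dem$gender),
        race_ethnicity = sample(names(dem$race_ethnicity), n,
            replace = TRUE, prob = dem$race_ethnicity),
        age_at_diagnosis = pmin(94L, pmax(19L,
            round(stats::rnorm(n, dem$age$median, ageSd)))),
        stringsAsFactors = FALSE)
    female <- patients$gender == "Female"

    gm <- config$genotype_model
    truthList <- list(); obsList <- list()
    for (gene in kb@genes$gene) {
        gAl <- gm[gm$gene == gene, , drop = FALSE]
        kbAl <- kbAlleles(kb, gene)
        ## KB allele order; alleles absent from the model get p = 0
        pHom <- gAl$p_hom[match(kbAl$allele, gAl$allele)]
        pHet <- gAl$p_het[match(kbAl$allele, gAl$allele)]
        pHom[is.na(pHom)] <- 0; pHet[is.na(pHet)] <- 0
        xLinked <- kb@genes$chromosome_mode[kb@genes$gene == gene] ==
            "x_linked"
        C <- .drawGeneCopies(n, pHom, pHet)
        hemi <- rep(FALSE, n)
        if (xLinked) {
            ## non-female carriers hold a single X copy
            male <- !female
            C[male, ] <- pmin(C[male, , drop = FALSE], 1L)
            hemi <- male & rowSums(C) > 0L
        }
        tot <- rowSums(C)
        refName <- kb@genes$reference_allele[kb@genes$gene == gene]
        a1 <- rep(refName, n); a2 <- rep(refName, n)
        carrier <- tot > 0L
        if (any(carrier)) {
            first <- max.col(C > 0L, ties.method = "first")
            last <- max.col(C > 0L, ties.method = "last")
            hom <- carrier & C[cbind(seq_len(n), first)] == 2L
            hemiC <- carrier & hemi
            a1[hom] <- kbAl$allele[first[hom]]
            a2[hom] <- kbAl$allele[first[hom]]
            het1 <- carrier & !hom & tot == 1L & !hemiC
            a2[het1] <- kbAl$allele[first[het1]]
            comp <- carrier & !hom & tot == 2L
            a1[comp] <- kbAl$allele[first[comp]]
            a2[comp] <- kbAl$allele[last[comp]]
            a1[hemiC] <- kbAl$allele[first[hemiC]]
            a2[hemiC] <- kbAl$allele[first[hemiC]]
        }
        cls <- rep("wild_type", n)
        cls[a2 != refName & a1 == refName] <- "heterozygous"
        cls[a1 != refName & a1 == a2] <- "homozygous_variant"
        cls[a1 != refName & a2 != refName & a1 != a2] <-
            "compound_heterozygous"
        cls[hemi] <- "hemizygous"
        truthList[[gene]] <- data.frame(patient = ids, gene = gene,
            allele1 = a1, allele2 = a2, carrier_class = cls,
            stringsAsFactors = FALSE)
        ## variant dosages implied by the planted copies
        vr <- kbVariants(kb, gene)
        vid <- unique(.variantId(vr$chrom, vr$pos, vr$ref, vr$alt))
        for (v in vid) {
            member <- vapply(kbAl$allele, function(al) {
                w <- vr$allele == al
                as.integer(v %in% .variantId(vr$chrom[w], vr$pos[w],
                    vr$ref[w], vr$alt[w]))
            }, integer(1L))
            dose <- as.integer(C %*% member)
            nz <- dose > 0L
            if (any(nz)) {
                vv <- vr[match(v, .variantId(vr$chrom, vr$pos, vr$ref,
                    vr$alt)), ]
                obsList[[length(obsList) + 1L]] <- data.frame(
                    patient = ids[nz], gene = gene, chrom = vv$chrom,
                    pos = vv$pos, ref = vv$ref, alt = vv$alt,
                    dosage = dose[nz], hemizygous = hemi[nz],
                    stringsAsFactors = FALSE)
            }
        }
    }
    truth <- do.call(rbind, c(truthList, make.row.names = FALSE))
    observations <- if (length(obsList)) do.call(rbind,
        c(obsList, make.row.names = FALSE)) else
        data.frame(patient = character(), gene = character(),
            chrom = character(), pos = integer(), ref = character(),
            alt = character(), dosage = integer(),
            hemizygous = logical())

    treatments <- .drawTreatments(patients, truth, config, kb)
    new("SyntheticCohort", patients = patients, truth = truth,
        observations = observations, treatments = treatments,
        config = config)
}

.drawTreatments <- function(patients, truth, config, kb) {
    tm <- config$treatment_model
    tox <- config$toxicity_model
    rules <- kbIndicationRules(kb)
    pairs <- kbDrugGenePairs(kb)
    carrierOf <- function(ids, gene) {
        t <- truth[truth$gene == gene, ]
        !t$carrier_class[match(ids, t$patient)] %in% "wild_type"
    }
    rows <- list()
    for (i in seq_len(nrow(rules))) {
        r <- rules[i, ]
        exp_p <- tm$exposure[[r$drug]][[r$tier]]
        if (is.null(exp_p) || exp_p <= 0) next
        inD <- patients$patient[patients$primary_site == r$disease]
        if (length(inD) == 0L) next
        treated <- inD[stats::runif(length(inD)) < exp_p]
        if (length(treated) == 0L) next
        here <- stats::runif(length(treated)) >= tm$treated_elsewhere
        pair <- pairs[pairs$drug == r$drug & pairs$gene == r$gene, ]
        isToxPair <- pair$association == "toxicity"
        carrier <- carrierOf(treated, r$gene)
        pTox <- ifelse(carrier, tox$variant_rate, tox$normal_rate)
        toxic <- isToxPair & here & stats::runif(length(treated)) < pTox
        nuis <- here & stats::runif(length(treated)) <
            tox$nuisance_event_rate
        evPool <- splitEvents(pair$events)
        events <- character(length(treated))
        actions <- character(length(treated))
        reason <- rep(NA_character_, length(treated))
        if (any(toxic)) {
            ev <- sample(evPool, sum(toxic), replace = TRUE)
            act <- sample(.GENOTOX_ACTIONS, sum(toxic), replace = TRUE)
            die <- stats::runif(sum(toxic)) < tox$death_given_toxicity
            act[die] <- "death"
            events[toxic] <- ev
            actions[toxic] <- act
            reason[toxic] <- ev
        }
        if (any(nuis)) {
            nev <- sample(.NUISANCE_EVENTS, sum(nuis), replace = TRUE)
            addTo <- which(nuis)
            events[addTo] <- ifelse(nzchar(events[addTo]),
                paste(events[addTo], nev, sep = ";"), nev)
            ## a nuisance event alone can still trigger an action, which
            ## the attribution rules must then exclude
            alone <- nuis & !toxic & isToxPair
            actions[alone] <- "discontinuation"
            reason[alone] <- nev[match(which(alone), addTo)]
        }
        rows[[length(rows) + 1L]] <- data.frame(patient = treated,
            drug = r$drug, received_here = here,
            adverse_events = events, actions = actions,
            action_reason = reason, stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L)
        return(data.frame(patient = character(), drug = character(),
            received_here = logical(), adverse_events = character(),
            actions = character(), action_reason = character(),
            stringsAsFactors = FALSE))
    out <- do.call(rbind, c(rows, make.row.names = FALSE))
    out[order(out$patient, out$drug), , drop = FALSE]
}

#' Write a synthetic cohort as VCF
#'
#' Emits valid VCF 4.2 with GRCh37 contigs and coverage-assertion header
#' lines (`##coveredregion=chr:start-end` spanning every panel
#' position), so that positions absent from the records are read back as
#' homozygous reference. Genotypes use the knowledge base's canonical
#' variant spellings; non-female samples are haploid on X.
#'
#' @param cohort a SyntheticCohort.
#' @param path output file (multi-sample) or directory (per-sample).
#' @param kb a KnowledgeBase.
#' @param multiSample one multi-sample file (default) or one file per
#'   patient.
#' @return the path(s) written, invisibly.
#' @export
emitVcf <- function(cohort, path, kb = loadKnowledgeBase(),
        multiSample = TRUE) {
    pat <- cohort@patients
    obs <- cohort@observations
    kbv <- kb@variants
    id <- .variantId(kbv$chrom, kbv$pos, kbv$ref, kbv$alt)
    keep <- !duplicated(id)
    sites <- data.frame(chrom = kbv$chrom[keep], pos = kbv$pos[keep],
        ref = kbv$ref[keep], alt = kbv$alt[keep],
        rsid = kbv$rsid[keep], gene = kbv$gene[keep],
        stringsAsFactors = FALSE)
    sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
    mode <- kb@genes$chromosome_mode[match(sites$gene, kb@genes$gene)]
    header <- c("##fileformat=VCFv4.2",
        "##source=pgxscreen-synthetic-cohort",
        sprintf("##contig=<ID=%s>", unique(sites$chrom)),
        sprintf("##coveredregion=%s:%d-%d", sites$chrom,
            pmax(1L, sites$pos - 100L), sites$pos + 100L),
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
    gtFor <- function(sampleIds) {
        female <- pat$gender[match(sampleIds, pat$patient)] == "Female"
        G <- matrix("0/0", nrow(sites), length(sampleIds))
        for (i in seq_len(nrow(sites))) {
            if (mode[i] == "x_linked") G[i, !female] <- "0"
        }
        if (nrow(obs) > 0L) {
            oid <- .variantId(obs$chrom, obs$pos, obs$ref, obs$alt)
            sid <- .variantId(sites$chrom, sites$pos, sites$ref,
                sites$alt)
            ri <- match(oid, sid); ci <- match(obs$patient, sampleIds)
            ok <- !is.na(ri) & !is.na(ci)
            gt <- ifelse(obs$hemizygous, "1",
                ifelse(obs$dosage == 2L, "1/1", "0/1"))
            G[cbind(ri[ok], ci[ok])] <- gt[ok]
        }
        G
    }
    writeOne <- function(file, sampleIds) {
        G <- gtFor(sampleIds)
        any1 <- rowSums(G == "0/0" | G == "0") < ncol(G)
        body <- if (any(any1)) {
            s <- sites[any1, , drop = FALSE]
            paste(s$chrom, s$pos,
                ifelse(is.na(s$rsid), ".", s$rsid), s$ref, s$alt,
                ".", "PASS", ".", "GT",
                apply(G[any1, , drop = FALSE], 1L, paste,
                    collapse = "\t"),
                sep = "\t")
        } else character()
        writeLines(c(header,
            paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                "FILTER", "INFO", "FORMAT", sampleIds),
                collapse = "\t"), body), file)
        file
    }
    if (multiSample) {
        invisible(writeOne(path, pat$patient))
    } else {
        dir.create(path, showWarnings = FALSE, recursive = TRUE)
        files <- vapply(pat$patient, function(s)
            writeOne(file.path(path, paste0(s, ".vcf")), s),
            character(1L))
        invisible(files)
    }
}

#' Write the clinical tables of a synthetic cohort
#'
#' Tab-delimited manifest, treatment and ground-truth tables with a
#' documented header contract and stable ordering, consumable by the
#' pipeline commands.
#'
#' @param cohort a SyntheticCohort.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
emitClinicalTables <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(manifest = file.path(dir, "manifest.tsv"),
        treatments = file.path(dir, "treatments.tsv"),
        truth = file.path(dir, "truth.tsv"))
    wr <- function(df, f) utils::write.table(df, f, sep = "\t",
        quote = FALSE, row.names = FALSE, na = "")
    wr(cohort@patients[order(cohort@patients$patient), ],
        files["manifest"])
    wr(cohort@treatments, files["treatments"])
    wr(cohort@truth[order(cohort@truth$patient, cohort@truth$gene), ],
        files["truth"])
    invisible(files)
}

## Table-3-marginal fixture: printed potential-risk numerators by
## (disease, gene); denominators come from the refined disease mix
.TABLE3_CELLS <- data.frame(
    disease = c("Colon/rectal", "Colon/rectal", "Pancreas", "Pancreas",
        "Gastric/gastroesophageal", "Gastric/gastroesophageal",
        "Cervix", "Cervix", "Ovary", "Ovary", "Ovary",
        "Hepatobiliary", "Carcinoid/neuroendocrine",
        "Small bowel adenocarcinoma", "Small bowel adenocarcinoma",
        "Breast", "Breast", "Acute lymphoblastic leukemia", "Uterus",
        "Head and neck", "Anus", "Vulva", "Basal cell skin",
        "Squamous cell skin", "Bladder", "Thyroid"),
    gene = c("UGT1A1", "DPYD", "UGT1A1", "DPYD", "UGT1A1", "DPYD",
        "UGT1A1", "DPYD", "UGT1A1", "DPYD", "CYP2D6", "UGT1A1",
        "UGT1A1", "UGT1A1", "DPYD", "DPYD", "CYP2D6", "TPMT", "CYP2D6",
        "DPYD", "DPYD", "DPYD", "DPYD", "DPYD", "DPYD", "DPYD"),
    carriers = c(33L, 3L, 7L, 1L, 4L, 1L, 1L, 0L, 16L, 2L, 1L, 5L, 6L,
        0L, 0L, 0L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)

#' Construct the risk-matrix marginal fixture cohort
#'
#' Builds a deterministic cohort whose per-disease sizes and per-(gene,
#' disease) carrier counts equal the published potential-risk marginals,
#' planting one representative heterozygous variant per carrier. Used to
#' check that the indication-matrix join reproduces every potential-risk
#' cell.
#'
#' @param kb a KnowledgeBase.
#' @return list(patients, calls): data.frames in the shapes expected by
#'   [potentialRisk()] / [riskMatrix()].
#' @export
table3FixtureCohort <- function(kb = loadKnowledgeBase()) {
    cfg <- defaultCalibration()
    counts <- round(cfg$disease_mix * 291)
    planted <- c(UGT1A1 = "*28", DPYD = "c.2846A>T", TPMT = "*2",
        CYP2D6 = "*6")
    pats <- list(); calls <- list(); idn <- 0L
    for (d in names(counts)) {
        nd <- counts[[d]]
        ids <- sprintf("F%05d", idn + seq_len(nd)); idn <- idn + nd
        pats[[d]] <- data.frame(patient = ids, primary_site = d,
            stringsAsFactors = FALSE)
        for (g in names(planted)) {
            k <- .TABLE3_CELLS$carriers[.TABLE3_CELLS$disease == d &
                .TABLE3_CELLS$gene == g]
            k <- if (length(k) == 0L) 0L else k[1L]
            refName <- kb@genes$reference_allele[kb@genes$gene == g]
            isCar <- seq_len(nd) <= k
            calls[[paste(d, g)]] <- data.frame(sample = ids, gene = g,
                allele1 = refName,
                allele2 = ifelse(isCar, planted[[g]], refName),
                carrier_class = ifelse(isCar, "heterozygous",
                    "wild_type"),
                ambiguous = FALSE, stringsAsFactors = FALSE)
        }
    }
    list(patients = do.call(rbind, c(pats, make.row.names = FALSE)),
        calls = do.call(rbind, c(calls, make.row.names = FALSE)))
}
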