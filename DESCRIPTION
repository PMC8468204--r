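Package: pgxscreen
Title: Universal Germline Pharmacogenomic Screening for Cancer Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Star-allele diplotype calling for a 15-gene CPIC level-A
        pharmacogene panel from germline VCF variant calls, metabolizer
        phenotype translation, disease-relevant actionability
        classification against an NCCN-derived drug-gene-indication
        matrix, genotype-related toxicity attribution, and cohort-level
        statistics (variant landscape, risk matrix, Fisher exact
        association). Ships an editable YAML knowledge base and a
        calibrated synthetic-cohort generator emitting VCFs and clinical
        tables with ground truth, so the full pipeline is testable
        end-to-end without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, yaml, jsonlite, vcfR
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: Pharmacogenomics, VariantAnnotation, Software
RoxygenNote: 7.3.3
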