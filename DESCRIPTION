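Package: eucrr
Title: Genome-Wide Recombination Rate Estimation in Eucalyptus Linkage Maps
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates meiotic recombination rate (RR, cM/Mb) in Eucalyptus
    globulus from genome-anchored linkage maps and analyses its variation
    between individuals and chromosomes and its association with genomic
    features. Provides the printed map summaries (10 parents x 11 chromosomes)
    and chromosome attribute tables as auditable fixtures; a meiosis simulator
    with known chromosome-specific recombination landscapes for parameter-
    recovery validation; CIP/CALP BLAST-anchoring of marker sequences;
    two-point recombination-fraction estimators (pseudo-testcross and
    F2-dominant maximum likelihood) with Haldane map distances along the fixed
    physical order; RR summaries at interval, chromosome and genome scale; and
    the statistical battery used on them: balanced two-way fixed-effects ANOVA
    with Type-3 sums of squares, Tukey-Kramer HSD with compact letter display,
    Pearson and first-order partial correlations, and pooled two-sample t-tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
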