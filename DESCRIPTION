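Package: ndjmap
Title: Crossover Mapping and Classification of Meiotic Nondisjunction from
    Pooled Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and analysis of spontaneous meiotic
    nondisjunction (NDJ) of a metacentric chromosome, modelled on Drosophila
    melanogaster chromosome 2. Simulates four-chromatid bivalents with
    configurable crossovers, meiosis I and meiosis II segregation errors,
    monosomy rescue, and pooled backcross sequencing with binomial read
    sampling; filters SNP read-count tables with depth and population-variance
    rules; segments per-sample allele-frequency tracks into genotype states
    with a binomial-emission Viterbi changepoint model and emits crossover
    calls with flanking-SNP resolution; classifies the erroneous meiotic
    division (MI vs MII) from pericentric heterozygosity, flags monosomy
    rescue candidates, and categorizes the likely cause of each NDJ event;
    and computes the comparative statistics (crossover-class fractions with
    the MII detection adjustment, arm association, coefficient of exchange,
    two-proportion z and Mann-Whitney tests) together with an exhaustive
    chromatid-inheritance detection-probability model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
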