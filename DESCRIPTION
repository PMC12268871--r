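Package: regcg
Title: Regularized Relative Entropy Minimization for Coarse-Grained Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bottom-up coarse-graining of molecular complexes with a
    regularized relative entropy minimization (reg-REM) trainer. Builds
    coarse-grained bead models from fine-grained reference ensembles
    (essential-dynamics bead mapping, heteroelastic network fitting of
    intramonomer springs, rule-based nonbonded constants from radial
    distribution functions), samples them with a Langevin dynamics engine
    (screened electrostatics, soft-core repulsion, Gaussian attraction
    wells), and learns the attraction amplitudes by Kullback-Leibler
    divergence descent regularized toward a target mean inter-molecular
    binding energy. Includes synthetic reference generators for bound
    dimers, lattice-like multimers and weakly bound chain pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
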