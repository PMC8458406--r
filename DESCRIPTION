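Package: coevdesign
Title: Coevolutionary Design of Hybrid Transcription Repressors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers a global Potts (direct coupling analysis) model from a
    protein-family multiple sequence alignment and uses it to design hybrid
    (chimeric) transcription repressors of the LacI family. Implements
    mean-field DCA with sequence reweighting and pseudocount regularisation,
    ranking of coevolving residue pairs by direct information or
    APC-corrected Frobenius norm, an inter-module compatibility score C(S)
    over top-ranked DNA-binding/ligand-binding module pairs, a structural
    fitness score SF(S) over crystal-structure contacts, and an in-silico
    mutational scanner that proposes and filters rescuing mutations for
    poorly functional hybrids. A Gibbs sampler and planted-coupling scenario
    generator provide fully synthetic test data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    bio3d,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
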