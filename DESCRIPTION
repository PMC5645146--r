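Package: uhskit
Title: Design and Evaluation of Universal k-mer Hitting Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes compact universal k-mer hitting sets: sets of k-mers
    such that every length-L string over an alphabet contains at least one
    member. Implements the optimal decycling phase on the complete de Bruijn
    graph (Mykkeltveit's construction), greedy path-cover heuristics driven
    by exact path-counting dynamic programming, an exact integer linear
    programming formulation, set verification and extension utilities, and
    a window-selection scanner for comparing hitting sets with minimizer
    schemes on sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with SciPy >= 1.9 on the PATH (exact
    ILP solver backend); C++11
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
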