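Package: rnanetdeg
Title: Expected Degree of RNA Secondary Structure Move-Set Networks
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exact dynamic-programming computation of the expected degree
    <N> = Q/Z of the network whose nodes are all secondary structures of an
    RNA sequence and whose edges are single moves of the folding-kinetics
    move sets MS1 (base-pair addition/removal), MS2 (addition/removal/shift)
    and the shift-only set MS2 minus MS1.  Three energy models are supported:
    a theta=1 homopolymer counting model with O(n^2) space recursions usable
    to n ~ 1000 and beyond, a uniform counting model for real sequences
    (Watson-Crick and wobble pairs, theta=3), and a Boltzmann-weighted model
    under a nearest-neighbour (Turner-style, no dangles) energy function via
    McCaskill-type partition-function recursions.  Includes an exhaustive
    enumeration oracle, structure-network construction and export, degree
    distributions, and the kinetic order parameters contact order, expected
    native contacts and conformational entropy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
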