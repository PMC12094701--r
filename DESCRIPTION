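Package: gridseq
Title: Sequence Codes of Trajectories on Hexagonal Lattices and Grid-Cell Map Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the sequence-code model of grid-cell firing: exhaustive
    enumeration of periodic arrangements of trajectory-coding elements on the
    hexagonal lattice, validity checking against the coding axioms, derivation
    of each arrangement's grid-map geometry (single-element sublattice, plane
    lattice type, axis repeat lengths, smallest angle to a wall), encoding and
    decoding of lattice trajectories as element sequences, phase-shifted
    multigrid stacks, a synthetic open-field session generator (correlated
    random-walk foraging, inhomogeneous Poisson spiking, occupancy-normalised
    smoothed rate maps, spatial autocorrelograms, grid score), and a
    re-implementation of the grid-field detection and spacing/size metrics
    pipeline (rate thresholding, density clustering, centroid geometry,
    central-field plus six-neighbour spacing, spacing-to-size ratio).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
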