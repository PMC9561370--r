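Package: nucbreathe
Title: Nucleosome Breathing Geometry, Protein-DNA Contact Maps and
    Collective Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of nucleosome conformational dynamics from
    molecular-dynamics trajectories or idealized models: breathing (linker
    opening) angles in a dyad-anchored coordinate frame, mass-weighted DNA
    radius of gyration, heavy-atom contact statistics between histone tails or
    transcription-factor subdomains and DNA regions with stable-contact
    profiling, and the weighted-minimum-distance (distanceInv) and
    coordination-number collective variables with declarative harmonic-wall
    and steered bias protocols exportable as Colvars-style configuration.
    Includes a seeded synthetic nucleosome generator that produces idealized
    168-bp nucleosome structures and breathing trajectories with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
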