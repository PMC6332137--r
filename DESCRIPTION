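Package: mtpaconf
Title: Conformational Survey of Crystalline MTPA (Mosher's) Amides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying the solid-state conformation of
    3,3,3-trifluoro-2-methoxy-2-phenylpropanamide (MTPA, Mosher) amide
    moieties in small-molecule crystal structures. Reads core CIF files,
    perceives bonds and locates MTPA-amide substructures, assigns the
    C2 stereodescriptor from signed volumes, computes the seven torsion
    descriptors of the amide survey (carbonyl/CF3 angle theta1,
    staggered-CF3 angle, amide planarity angles, methine angle,
    methoxy/phenyl angle theta2 and methoxy rotamer), mirror-normalizes
    S-acid records to the R-acid frame, classifies conformers (theta1
    window, CF3 stagger, amide Z/E form, Mosher type, carbonyl/methoxy
    syn-anti) and reproduces the survey statistics: seam-aware medians,
    windowed means with exclusion ledgers, 10-degree histograms and
    categorical tallies. Ships the 58-moiety reference torsion table and
    an internal-coordinate generator of synthetic MTPA-amide structures
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
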