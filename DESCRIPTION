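Package: cardiomark
Title: Marker-Based Cardiac Kinematics from Biplane Videofluoroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing and analysing the motion of radiopaque
    markers implanted on the beating heart and imaged with calibrated biplane
    X-ray videofluoroscopy. Provides a synthetic beating-heart marker simulator
    (35-marker tricuspid/ventricular array at 500 Hz), planar-target camera
    calibration with direct linear transform and epipolar geometry, two-stage
    graph-based multi-marker 3D tracking (tracklet extraction by successive
    shortest paths in a directed acyclic observation graph, then tracklet
    linking), automated anatomical marker identification by guide-marker-seeded
    similarity registration and optimal bipartite matching, and quantitative
    tricuspid annular and ventricular geometry metrics (annular fan area,
    least-squares annular plane height profile, septal-lateral diameters,
    leaflet opening angle, apex-annulus distances, regional and total
    ventricular surface areas, and beat-phase landmarks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    clue,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
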