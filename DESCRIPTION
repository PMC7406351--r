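Package: echojam
Title: Sensorimotor Simulation of Echolocating Bats Foraging in Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based sensorimotor simulation of FM-echolocating bats
    hunting erratically flying prey in a bounded two-dimensional arena.  The
    package implements the full acoustics chain (sonar equation, circular
    piston directivity for mouth and ear, atmospheric absorption, disc target
    strength, conspecific calls and bistatic conspecific echoes, border
    clutter), two alternative auditory receivers (an optimal matched-filter
    correlation receiver with forward/backward masking windows, and an
    80-channel gammatone filter-bank with envelope detection and de-chirp
    summation), distance-dependent echolocation phase control
    (search/approach/buzz), a spectral jamming avoidance response (JAR), and
    trial- and experiment-level metrics such as jamming probability, masking
    effect and the emergent frequency shift of bats flying in groups.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
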