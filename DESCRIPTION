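Package: netcontagion
Title: Passive, Active and Mixed Contagion Models on Complex Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation of innovation and idea diffusion on undirected social
    networks under three synchronous contagion schemes: a deterministic
    linear-threshold model driven by peer pressure, a stochastic node-profile
    model driven by personal preference, and a mixed profile-threshold model
    that gates preference trials behind a peer-pressure threshold. Supports
    permanently blocked (refusing) nodes, spontaneous exogenous adoption,
    Barabasi-Albert, Erdos-Renyi and Watts-Strogatz graph generators, plain
    edge-list input and output, a multi-seed-set experimental protocol with
    iteration-wise trend averaging, parameter-grid sweeps, and a command-line
    interface with reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
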