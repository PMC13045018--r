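Package: pyrosom
Title: Pyrolysis GC/MS and Evolved Gas Analysis Workflow for Soil Organic Matter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable workflow for molecular characterization of
    soil organic matter by pyrolysis gas chromatography/mass spectrometry
    (py-GC/MS) and evolved gas analysis (EGA/MS). Provides mzML/MSP/MGF
    readers and writers, extracted-ion chromatogram construction, peak
    detection, multivariate curve resolution (non-negative alternating least
    squares) of co-eluting pyrolysates, cross-sample feature alignment with a
    blended retention-time/spectral score, cosine library annotation with a
    12-class compound classification, fragmentation-spectrum molecular
    networking (edge threshold, mutual TopK pruning, singleton exclusion)
    with class propagation to unannotated nodes, ecological statistics
    (Shannon and Gini-Simpson diversity, Bray-Curtis dissimilarity,
    permutation-based PERMANOVA, hierarchical clustering, Pearson profile
    correlation), evolved-gas thermal profiling with high-temperature
    inorganic-carbon flagging, and a ground-truthed synthetic-data generator
    so that every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    mzR,
    igraph,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'alignment.R'
    'annotate.R'
    'deconvolution.R'
    'ecostats.R'
    'ega.R'
    'networking.R'
    'pipeline.R'
    'pyrosom-package.R'
    'spectra-io.R'
    'synthetic.R'
    'utils.R'
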