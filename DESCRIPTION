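Package: posquant
Title: Quantification of Photoreceptor Outer Segments in Microscopy Images
Version: 0.1.0
Authors@R:
    person("posquant", "developers", email = "posquant@example.org",
           role = c("aut", "cre"))
Description: Two complementary toolchains for quantifying photoreceptor outer
    segments (POS) on retinal sections. The TEM arm measures the nematic
    orientation and coherency (scalar nematic order parameter) of POS membrane
    stacks on transmission electron microscopy images from the image intensity
    gradient, using an optimized 5x5 derivative operator, per-ROI local and
    global coherency, and per-replicate angle alignment. The LM arm segments
    S-opsin labelled cone outer segments on 3D fluorescence stacks with a
    random-forest pixel classifier over a convolutional feature bank, validates
    predictions against reference annotations, and extracts per-object number,
    size, shape and intensity features after isotropic rescaling, followed by
    the replicate-averaged group statistics. Includes synthetic image
    generators with ground truth, and readers/writers for plain grayscale TIFF
    and ImageJ ROI files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
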