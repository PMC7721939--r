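Package: Y90dosimetry
Title: Pre-Treatment Dosimetry for Y-90 Radioembolization from Tc-99m-MAA Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Planning dosimetry for yttrium-90 radioembolization of hepatic
    malignancies based on technetium-99m macroaggregated-albumin (MAA)
    scintigraphy. Computes the lung shunt fraction from anterior/posterior
    planar counts, mean absorbed doses with the MIRD partition model and a
    multi-tumor partition model that resolves individual tumors, and 3-D
    voxel dose maps by the local deposition method and by dose-point-kernel
    convolution. Includes cumulative dose-volume histogram metrics
    (D5..D95, V20, V100), method-agreement statistics (Bland-Altman limits,
    Lin concordance, normalized mean square error, voxel difference maps),
    NIfTI input/output, and a synthetic SPECT-like liver phantom generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, RNifti, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
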