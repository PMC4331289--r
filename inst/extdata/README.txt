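Confusion-matrix fixtures re-entered from the printed accuracy tables of
the original CROPCLASS validation campaign (LaVentilla area, Southern
Spain, 2010; seven multispectral acquisitions April-October, 311 surveyed
census parcels, half used for training and half for testing).

training_*  : decision-tree training-model evaluation (156 parcels)
testing_*   : phase-II classification of the unidentified parcels
*_crops     : all individual crops / land uses (15 classes)
*_ato/suc/wic : per-cropping-system panels (adult tree orchards, summer
              crops, winter crops)

Format: tab-delimited; rows = observed class, columns = predicted class.
Notes kept as printed rather than "fixed":
  - training_ato uses the class code ORT exactly as printed (13 parcels;
    elsewhere the same parcels are coded CIT).
  - the printed per-row "predicted" count for the testing SUC SUN row (6)
    is inconsistent with its own cells (2 + 8); the cell counts are used.
  - printed OA values were evidently truncated in places (e.g. the
    all-crops training OA prints 80.7 while the cells give 80.769...).
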