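# Curated snapshot of well-known cancer/testis (cancer germline) antigen
# gene symbols; a partial snapshot of the community CT antigen catalogue,
# one symbol per line. Replaceable by any user-supplied list.
MAGEA1
MAGEA2
MAGEA3
MAGEA4
MAGEA6
MAGEA8
MAGEA9
MAGEA10
MAGEA11
MAGEA12
MAGEB1
MAGEB2
MAGEB3
MAGEB4
MAGEB6
MAGEC1
MAGEC2
MAGEC3
CTAG1B
CTAG2
GAGE1
GAGE2A
GAGE4
GAGE12I
PAGE1
PAGE2
PAGE4
XAGE1A
XAGE2
XAGE3
BAGE
SSX1
SSX2
SSX4
SPANXA1
SPANXB1
SPANXC
SPANXD
PRAME
NY-SAR-35
CT45A1
CT47A1
CT83
SAGE1
HORMAD1
HORMAD2
LAGE3
PASD1
CTCFL
TSP50
BRDT
TEX14
TEX15
ODF1
ODF2
AKAP3
AKAP4
SPA17
SPO11
SYCP1
TDRD1
PIWIL2
DDX43
DDX53
FATE1
FMR1NB
LUZP4
TTK
CABYR
THEG
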