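"name","primary","alternate"
"ADAMS","ATMS","ATMS"
"ALEXANDER","ALKS","ALKS"
"AMY","AM","AM"
"ANGUS","ANKS","ANKS"
"ARNOLD","ARNL","ARNL"
"AUGUSTUS","AKST","AKST"
"BARRACLOUGH","PRKL","PRKL"
"BENJAMIN","PNJM","PNJM"
"BERRY","PR","PR"
"BETTY","PT","PT"
"BOTTOMLEY","PTML","PTML"
"BOYD","PT","PT"
"BRADLEY","PRTL","PRTL"
"BRADSHAW","PRTX","PRTX"
"BRIAN","PRN","PRN"
"CAMPBELL","KMPL","KMPL"
"CHAMBERS","XMPR","XMPR"
"CHARLESWORTH","XRLS","XRLS"
"CLARKE","KLRK","KLRK"
"COCKCROFT","KKKR","KKKR"
"CRYER","KRR","KRR"
"CUNNINGHAM","KNNK","KNNK"
"DANIEL","TNL","TNL"
"DAY","T","T"
"DENISE","TNS","TNS"
"DONNA","TN","TN"
"EDWINA","ATN","ATN"
"ERIC","ARK","ARK"
"ERNEST","ARNS","ARNS"
"EUPHEMIA","AFM","AFM"
"FERGUSON","FRKS","FRKS"
"FITZPATRICK","FTSP","FTSP"
"FRANCES","FRNS","FRNS"
"FREDERICK","FRTR","FRTR"
"GARZA","KRS","KRS"
"GLORIA","KLR","KLR"
"GOODALL","KTL","KTL"
"GREENE","KRN","KRN"
"GREGORY","KRKR","KRKR"
"HAIG","HK","HK"
"HANNAH","HN","HN"
"HANSEN","HNSN","HNSN"
"HARPER","HRPR","HRPR"
"HART","HRT","HRT"
"HARVEY","HRF","HRF"
"HAZEL","HSL","HSL"
"HENDERSON","HNTR","HNTR"
"HERBERT","HRPR","HRPR"
"HOLROYD","HLRT","HLRT"
"HOWELL","HL","HL"
"ILLINGWORTH","ALNK","ALNK"
"INGHAM","ANKM","ANKM"
"JACK","JK","AK"
"JACOB","JKP","AKP"
"JAMES","JMS","AMS"
"JANICE","JNS","ANS"
"JASON","JSN","ASN"
"JEAN","JN","AN"
"JENNIFER","JNFR","ANFR"
"JEROME","JRM","ARM"
"JESSICA","JSK","ASK"
"JOAN","JN","AN"
"JOHNNY","JN","AN"
"JOHNSTON","JNST","ANST"
"JOHNSTONE","JNST","ANST"
"JOWETT","JT","AT"
"JUAN","JN","AN"
"JUDITH","JT0","ATT"
"KATHLEEN","K0LN","KTLN"
"KELLY","KL","KL"
"KERSHAW","KRX","KRXF"
"KINCAID","KNKT","KNKT"
"LORI","LR","LR"
"LUCILLE","LSL","LSL"
"LUMB","LM","LM"
"MACDONALD","MKTN","MKTN"
"MAEVE","MF","MF"
"MALLINSON","MLNS","MLNS"
"MARGARET","MRKR","MRKR"
"MATILDA","MTLT","MTLT"
"MAXWELL","MKSL","MKSL"
"MEGAN","MKN","MKN"
"MELANIE","MLN","MLN"
"MICHELLE","MXL","MKL"
"MILLICENT","MLSN","MLSN"
"MITCHELL","MXL","MXL"
"NANCY","NNS","NNS"
"NOAH","N","N"
"NOBLE","NPL","NPL"
"OCONNOR","AKNR","AKNR"
"OGDEN","AKTN","AKTN"
"OGILVIE","AJLF","AKLF"
"OLSON","ALSN","ALSN"
"ONEILL","ANL","ANL"
"PAMELA","PML","PML"
"PARKER","PRKR","PRKR"
"PAUL","PL","PL"
"PEARL","PRL","PRL"
"PHILLIPS","FLPS","FLPS"
"PICKERING","PKRN","PKRN"
"POPPLEWELL","PPLL","PPLL"
"POPPY","PP","PP"
"RALPH","RLF","RLF"
"RAMSDEN","RMST","RMST"
"REBECCA","RPK","RPK"
"REDMAN","RTMN","RTMN"
"RHODES","RTS","RTS"
"ROSS","RS","RS"
"RUBY","RP","RP"
"RUDOLPH","RTLF","RTLF"
"RUTH","R0","RT"
"SAMUEL","SML","SML"
"SCHOFIELD","XFLT","XFLT"
"SENIOR","SNR","SNR"
"SHACKLETON","XKLT","XKLT"
"SIDNEY","STN","STN"
"SIMS","SMS","SMS"
"STELLA","STL","STL"
"STEWART","STRT","STRT"
"SULLIVAN","SLFN","SLFN"
"SUTCLIFFE","STKL","STKL"
"TAMARA","TMR","TMR"
"THERESA","0RS","TRS"
"TINKER","TNKR","TNKR"
"TOBIAS","TPS","TPS"
"UTTLEY","ATL","ATL"
"VALERIE","FLR","FLR"
"VASQUEZ","FSKS","FSKS"
"VICTORIA","FKTR","FKTR"
"VIRGINIA","FRJN","FRKN"
"WADDINGTON","ATNK","FTNK"
"WADSWORTH","ATSR","FTSR"
"WATSON","ATSN","FTSN"
"WAYNE","AN","FN"
"WHEELER","ALR","ALR"
"WILSON","ALSN","FLSN"
"WOOD","AT","FT"
"YOUNG","ANK","ANK"
"ZACHARY","SKR","SKR"
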