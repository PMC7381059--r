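name
ABBOTT
ACKROYD
ADAMS
ALLEN
ALVAREZ
ANDERSON
ANDREWS
APPLEYARD
ARMSTRONG
ARNOLD
ASQUITH
AUSTIN
BAIRSTOW
BAKER
BAMFORTH
BANKS
BARKER
BARNES
BARRACLOUGH
BATTY
BEAUMONT
BELL
BENNETT
BERRY
BINNS
BISHOP
BLACKBURN
BOLTON
BOOTH
BOTTOMLEY
BOYD
BRADLEY
BRADSHAW
BRENNAN
BRIGGS
BROADBENT
BROOKS
BROWN
BRUCE
BRYANT
BULLOCK
BURKE
BURNS
BUTLER
BUTTERFIELD
CALLAGHAN
CAMERON
CAMPBELL
CARPENTER
CARR
CARROLL
CARTER
CARTWRIGHT
CASTILLO
CHADWICK
CHAMBERS
CHAPMAN
CHARLESWORTH
CHIPPINDALE
CHRISTENSEN
CLARKE
CLAYTON
CLEGG
CLOUGH
COCHRANE
COCKCROFT
COLE
COLLINS
COOK
COOPER
CRABTREE
CRAWFORD
CROSSLEY
CRYER
CUDWORTH
CUNNINGHAM
DALGLEISH
DAVIS
DAWSON
DAY
DENT
DIXON
DOHERTY
DOUGLAS
DOYLE
DRUMMOND
DUNCAN
DUNN
DYSON
EARNSHAW
ECCLES
EDWARDS
ELLIOTT
ELLIS
ELPHINSTONE
EMMOTT
EVANS
FAIRBANK
FEATHER
FERGUSON
FERNANDEZ
FIELDS
FIRTH
FISHER
FITZGERALD
FITZPATRICK
FORD
FOSTER
FOWLER
FRANKLIN
FRASER
GALBRAITH
GARDNER
GARSIDE
GARZA
GAUNT
GIBSON
GLEDHILL
GOODALL
GORDON
GRAHAM
GRANT
GRAY
GREEN
GREENE
GREENWOOD
GUTIERREZ
HAIG
HAIGH
HAINSWORTH
HALL
HAMILTON
HANSEN
HANSON
HARGREAVES
HARPER
HARRIS
HARRISON
HART
HARVEY
HAWKINS
HAYES
HELLIWELL
HENDERSON
HEPWORTH
HILL
HINCHCLIFFE
HIRST
HOBSON
HOLDSWORTH
HOLROYD
HORSFALL
HOWELL
HOYLE
HUDSON
HUGHES
ILLINGWORTH
INGHAM
IRVINE
JAGGER
JAMES
JARDINE
JOHNSON
JOHNSTON
JOHNSTONE
JONES
JORDAN
JOWETT
KAVANAGH
KAYE
KELLY
KENNEDY
KENNY
KERR
KERSHAW
KILNER
KINCAID
KING
LANE
LARSON
LAWRENCE
LAWSON
LEE
LENNOX
LINDSAY
LONGBOTTOM
LUMB
LUND
MACDONALD
MACK
MACKENZIE
MACLEOD
MALLINSON
MARSDEN
MARSHALL
MARTIN
MATTHEWS
MAXWELL
MCCARTHY
MCCOY
MCDONALD
MELVILLE
MEYER
MIDGLEY
MILLS
MITCHELL
MOLONEY
MONTGOMERY
MOORE
MORGAN
MORRIS
MORRISON
MURGATROYD
MURPHY
MURRAY
NAPIER
NAYLOR
NELSON
NGUYEN
NOBLE
O'BRIEN
O'CONNOR
O'NEILL
OATES
OGDEN
OGILVIE
OLIVER
OLSON
OWENS
PALMER
PARKER
PARKINSON
PATERSON
PATTERSON
PAYNE
PEEL
PERKINS
PETERS
PHILLIPS
PICKERING
PICKLES
PIERCE
POPPLEWELL
POWELL
PRATT
PRICE
PRIESTLEY
PRINGLE
QUINN
RAMSAY
RAMSDEN
RAWNSLEY
RAY
REDMAN
REYNOLDS
RHODES
RICHARDS
RIVERA
ROBERTS
ROBERTSHAW
ROBINSON
ROEBUCK
ROGERS
ROSS
RUIZ
RUTHERFORD
RYAN
SALAZAR
SANDERS
SCHMIDT
SCHOFIELD
SCOTT
SENIOR
SHACKLETON
SHARP
SHAW
SHEEHAN
SIMPSON
SIMS
SINCLAIR
SMITH
SNYDER
SOMERVILLE
SPENCER
STANLEY
STEPHENS
STEWART
STONE
SUGDEN
SULLIVAN
SUNDERLAND
SUTCLIFFE
SWALLOW
SYKES
TATE
TAYLOR
TEAL
TENNANT
THACKERAY
THEWLIS
THOMAS
THOMPSON
THORNTON
TINKER
TOWNEND
TURNER
URQUHART
UTTLEY
VASQUEZ
VERITY
WADDINGTON
WADSWORTH
WAGNER
WALKER
WALLACE
WALSH
WATKINS
WATSON
WAUGH
WEAVER
WELLS
WEST
WHEELER
WHELAN
WHITAKER
WHITE
WHITELEY
WILDE
WILLIAMS
WILLIAMSON
WILLIS
WILSON
WOMBWELL
WOOD
WOODHEAD
WORSNOP
WRIGHT
YOUNG
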