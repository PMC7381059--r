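nickname,formal
ABBY,ABIGAIL
ABE,ABRAHAM
AL,ALBERT
ALEC,ALEXANDER
ALEX,ALEXANDER
ALFIE,ALFRED
ANDY,ANDREW
ANGIE,ANGELA
ANNIE,ANNE
ARCHIE,ARCHIBALD
ARTIE,ARTHUR
BARB,BARBARA
BARNEY,BERNARD
BART,BARTHOLOMEW
BEA,BEATRICE
BECKY,REBECCA
BEL,ISABEL
BEN,BENJAMIN
BENNY,BENJAMIN
BERT,ALBERT
BESS,ELIZABETH
BETH,ELIZABETH
BETSY,ELIZABETH
BETTY,ELIZABETH
BILL,WILLIAM
BILLY,WILLIAM
BOB,ROBERT
BOBBY,ROBERT
BRAD,BRADLEY
CAM,CAMERON
CARRIE,CAROLINE
CASSIE,CASSANDRA
CATHY,CATHERINE
CHARLIE,CHARLES
CHAS,CHARLES
CHRIS,CHRISTOPHER
CHRISSY,CHRISTINE
CHUCK,CHARLES
CINDY,CYNTHIA
CLIFF,CLIFFORD
CONNIE,CONSTANCE
DAN,DANIEL
DANNY,DANIEL
DAVE,DAVID
DEB,DEBORAH
DEBBIE,DEBORAH
DEE,DOROTHY
DENNY,DENNIS
DICK,RICHARD
DOLLY,DOROTHY
DON,DONALD
DONNY,DONALD
DOT,DOROTHY
DOUG,DOUGLAS
DREW,ANDREW
ED,EDWARD
EDDIE,EDWARD
EFFIE,EUPHEMIA
ELIZA,ELIZABETH
ELLIE,ELEANOR
EM,EMILY
EMMY,EMILY
ERNIE,ERNEST
FANNY,FRANCES
FLO,FLORENCE
FRAN,FRANCES
FRANK,FRANCIS
FRANKIE,FRANCIS
FRED,FREDERICK
FREDDIE,FREDERICK
GAB,GABRIEL
GABE,GABRIEL
GAIL,ABIGAIL
GEOFF,GEOFFREY
GERRY,GERALD
GINA,REGINA
GINNY,VIRGINIA
GREG,GREGORY
GUS,AUGUSTUS
HAL,HAROLD
HANK,HENRY
HARRY,HENRY
HATTIE,HARRIET
HERB,HERBERT
HUGO,HUGH
IKE,ISAAC
IZZY,ISABELLA
JACK,JOHN
JACKIE,JACQUELINE
JAKE,JACOB
JAN,JANET
JEB,JEBEDIAH
JEFF,JEFFREY
JEN,JENNIFER
JENNY,JENNIFER
JERRY,JEROME
JESS,JESSICA
JESSIE,JESSICA
JIM,JAMES
JIMMY,JAMES
JO,JOSEPHINE
JOE,JOSEPH
JOEY,JOSEPH
JOHNNY,JOHN
JON,JONATHAN
JOSH,JOSHUA
JUDY,JUDITH
JULES,JULIAN
KATE,KATHERINE
KATHY,KATHERINE
KATIE,KATHERINE
KEN,KENNETH
KENNY,KENNETH
KIT,CHRISTOPHER
LARRY,LAWRENCE
LEN,LEONARD
LENNY,LEONARD
LEO,LEONARD
LES,LESLIE
LIBBY,ELIZABETH
LIZ,ELIZABETH
LIZZIE,ELIZABETH
LOU,LOUIS
LOUIE,LOUIS
LUCY,LUCILLE
MAGGIE,MARGARET
MANDY,AMANDA
MARGE,MARGARET
MARTY,MARTIN
MAT,MATTHEW
MATT,MATTHEW
MAX,MAXWELL
MEG,MARGARET
MEL,MELANIE
MICK,MICHAEL
MICKEY,MICHAEL
MIKE,MICHAEL
MILLIE,MILLICENT
MINNIE,WILHELMINA
MITCH,MITCHELL
MOLL,MARY
MOLLY,MARY
NAN,NANCY
NATE,NATHANIEL
NED,EDWARD
NELL,ELEANOR
NICK,NICHOLAS
NICKY,NICHOLAS
NORM,NORMAN
OLLIE,OLIVER
PAM,PAMELA
PAT,PATRICIA
PATSY,PATRICIA
PATTY,PATRICIA
PEG,MARGARET
PEGGY,MARGARET
PETE,PETER
PHIL,PHILIP
POLLY,MARY
RAY,RAYMOND
REG,REGINALD
RICH,RICHARD
RICK,RICHARD
RICKY,RICHARD
ROB,ROBERT
ROBBIE,ROBERT
ROD,RODNEY
RON,RONALD
RONNIE,RONALD
ROSIE,ROSEMARY
ROXY,ROXANNE
RUDY,RUDOLPH
RUSS,RUSSELL
SAL,SALLY
SAM,SAMUEL
SAMMY,SAMUEL
SANDY,SANDRA
SHEL,SHELDON
SID,SIDNEY
STAN,STANLEY
STEVE,STEPHEN
STEVIE,STEPHEN
STEW,STEWART
SUE,SUSAN
SUSIE,SUSAN
TAM,TAMARA
TED,EDWARD
TEDDY,EDWARD
TERRY,TERENCE
TESS,THERESA
THEO,THEODORE
TIM,TIMOTHY
TIMMY,TIMOTHY
TINA,CHRISTINA
TOBY,TOBIAS
TOM,THOMAS
TOMMY,THOMAS
TONY,ANTHONY
TRICIA,PATRICIA
TRISH,PATRICIA
VAL,VALERIE
VIC,VICTOR
VICKY,VICTORIA
VINNY,VINCENT
WALT,WALTER
WENDY,GWENDOLYN
WILL,WILLIAM
WILLY,WILLIAM
ZACH,ZACHARY
ZAK,ZACHARY
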