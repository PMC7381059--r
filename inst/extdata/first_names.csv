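name
AARON
ABIGAIL
ADAM
ALAN
ALBERT
ALEXANDER
ALEXIS
ALICE
AMANDA
AMBER
AMELIA
AMY
ANDREA
ANDREW
ANGELA
ANGUS
ANN
ANNA
ANTHONY
ARTHUR
ASHLEY
AUDREY
AUGUSTUS
AUSTIN
BARBARA
BEATRICE
BENJAMIN
BERNARD
BETTY
BEVERLY
BILLY
BOBBY
BRADLEY
BRANDON
BRENDA
BRIAN
BRITTANY
BRONWYN
BRUCE
BRYAN
CAITLIN
CAMERON
CARL
CAROL
CAROLYN
CASSANDRA
CATHERINE
CHARLES
CHARLOTTE
CHERYL
CHLOE
CHRISTIAN
CHRISTINA
CHRISTINE
CLARA
CLIFFORD
CONSTANCE
CYNTHIA
DAISY
DANIEL
DANIELLE
DAVID
DEBORAH
DEBRA
DENISE
DENNIS
DIANA
DIANE
DONNA
DORIS
DOROTHY
DOUGLAS
DUNCAN
DYLAN
EDWARD
EDWINA
ELEANOR
ELIJAH
ELIZABETH
ELSIE
EMILY
EMMA
ERIC
ERNEST
ETHAN
EUGENE
EUPHEMIA
EVELYN
FLORENCE
FRANCES
FRANK
FREDERICK
FREYA
GABRIEL
GARY
GEOFFREY
GEORGE
GERALD
GLORIA
GRACE
GREGOR
GREGORY
GWENDOLYN
HAMISH
HANNAH
HAROLD
HARRIET
HAZEL
HEATHER
HELEN
HENRY
HERBERT
HUGH
IMOGEN
IRENE
ISAAC
ISABELLA
IVY
JACK
JACOB
JACQUELINE
JAMES
JANET
JANICE
JASON
JEAN
JEFFREY
JENNIFER
JEREMY
JEROME
JERRY
JESSE
JESSICA
JOAN
JOE
JOHN
JOHNNY
JONATHAN
JORDAN
JOSE
JOSEPH
JOSHUA
JOYCE
JUAN
JUDITH
JUDY
JULIA
JULIE
JUSTIN
KAREN
KATHERINE
KATHLEEN
KATHRYN
KAYLA
KEITH
KELLY
KENNETH
KEVIN
KIMBERLY
KYLE
LACHLAN
LARRY
LAURA
LAUREN
LAWRENCE
LEONARD
LINDA
LISA
LOGAN
LORI
LOUIS
LUCILLE
MABEL
MADISON
MAEVE
MARGARET
MARIA
MARIE
MARILYN
MARK
MARTHA
MARTIN
MARY
MATILDA
MATTHEW
MAXWELL
MEGAN
MELANIE
MELISSA
MICHAEL
MICHELLE
MILLICENT
MITCHELL
NANCY
NATALIE
NATHAN
NICHOLAS
NICOLE
NOAH
NORA
NORMAN
OLIVIA
PAMELA
PATRICIA
PATRICK
PAUL
PEARL
PETER
PHILIP
PHOEBE
POPPY
RACHEL
RALPH
RANDY
RAYMOND
REBECCA
REGINA
REGINALD
RICHARD
ROBERT
RODNEY
ROGER
RONALD
ROSEMARY
ROXANNE
ROY
RUBY
RUDOLPH
RUSSELL
RUTH
RYAN
SALLY
SAMANTHA
SAMUEL
SANDRA
SARA
SARAH
SCOTT
SEAN
SHARON
SHELDON
SHIRLEY
SIDNEY
SIOBHAN
SOPHIA
STANLEY
STELLA
STEPHANIE
STEPHEN
STEWART
SUSAN
TAMARA
TERESA
TERRY
THEODORE
THERESA
THOMAS
TIMOTHY
TOBIAS
TYLER
VALERIE
VERA
VICTOR
VICTORIA
VINCENT
VIRGINIA
WALTER
WAYNE
WILHELMINA
WILLIAM
WILLIE
ZACHARY
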